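#' Configuration for synthetic assemblages
#'
#' The generator emulates the statistical structure a multi-dimension trait
#' compilation must have for niche-scheme methods to work: within each niche
#' dimension, species cluster around adaptive peaks in trait space; a latent
#' cross-dimension gradient induces inter-block correlation; and mean
#' abundance carries a planted correlation with that gradient. Defaults
#' mirror the scale of a well-studied tropical fish assemblage: 56 species,
#' five dimensions with 8+8+8+7+7 = 38 traits, per-dimension peak counts
#' (4, 5, 6, 2, 6), and 12 monthly abundance surveys.
#'
#' @param n_species number of species.
#' @param dimensions niche dimension labels (subset of [NICHE_DIMENSIONS]).
#' @param n_traits per-dimension trait counts (recycled).
#' @param n_groups per-dimension adaptive-peak counts (recycled, all >= 1).
#' @param peak_separation minimum distance between peak centres, in units of
#'   `noise_sd` (default 6: cleanly separated groups).
#' @param noise_sd within-peak trait standard deviation (> 0).
#' @param gradient_strength loading of the latent cross-dimension gradient on
#'   every trait block, in units of `noise_sd`.
#' @param response_rho planted natural-scale correlation between the latent
#'   gradient and mean abundance (|rho| <= 1).
#' @param abundance_sigma log-scale standard deviation of species abundance
#'   (lognormal marginal; ecological abundances are right-skewed).
#' @param survey_sigma log-scale survey-to-survey noise per month.
#' @param n_surveys number of abundance surveys (>= 2).
#' @param seed integer seed; the whole assemblage is reproducible from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_species = 56L,
                       dimensions = NICHE_DIMENSIONS,
                       n_traits = c(8L, 8L, 8L, 7L, 7L),
                       n_groups = c(4L, 5L, 6L, 2L, 6L),
                       peak_separation = 6,
                       noise_sd = 1,
                       gradient_strength = 0.5,
                       response_rho = 0.5,
                       abundance_sigma = 1,
                       survey_sigma = 0.2,
                       n_surveys = 12L,
                       seed = 1L) {
  dimensions <- vapply(dimensions, match.arg, character(1), NICHE_DIMENSIONS)
  nd <- length(dimensions)
  n_traits <- rep_len(as.integer(n_traits), nd)
  n_groups <- rep_len(as.integer(n_groups), nd)
  if (any(n_groups < 1L)) stop_ns("n_groups must all be >= 1")
  if (noise_sd <= 0) stop_ns("noise_sd must be > 0")
  if (abs(response_rho) > 1) stop_ns("|response_rho| must be <= 1")
  if (n_species < max(n_groups)) {
    stop_ns("n_species (", n_species, ") < largest n_groups (", max(n_groups), ")")
  }
  if (n_surveys < 2L) stop_ns("n_surveys must be >= 2")
  structure(
    list(n_species = as.integer(n_species), dimensions = unname(dimensions),
         n_traits = n_traits, n_groups = n_groups,
         peak_separation = peak_separation, noise_sd = noise_sd,
         gradient_strength = gradient_strength, response_rho = response_rho,
         abundance_sigma = abundance_sigma, survey_sigma = survey_sigma,
         n_surveys = as.integer(n_surveys), seed = as.integer(seed)),
    class = "sim_config"
  )
}

# k peak centres in R^p with pairwise distance >= sep: evenly spaced on a
# circle of radius sep / (2 sin(pi/k)) inside a random 2-D subspace
place_peaks <- function(k, p, sep) {
  if (k == 1L) return(matrix(0, 1L, p))
  if (p == 1L) {
    return(matrix(sep * (seq_len(k) - (k + 1) / 2), k, 1L))
  }
  basis <- qr.Q(qr(matrix(stats::rnorm(p * 2L), p, 2L)))
  r <- sep / (2 * sin(pi / k))
  theta <- 2 * pi * (seq_len(k) - 1L) / k + stats::runif(1L, 0, 2 * pi)
  cbind(cos(theta), sin(theta)) %*% t(basis) * r
}

# log-scale correlation needed so that corr(gradient, computed mean
# abundance) equals rho on the natural scale: for A = exp(sigma * L) with
# corr(g, L) = rho_log and independent survey-mean noise of variance v_f,
# corr(g, A * F) = rho_log * sigma / sqrt(exp(sigma^2) (1 + v_f) - 1).
calibrate_rho_log <- function(rho, sigma, survey_sigma, n_surveys) {
  v_f <- (exp(survey_sigma^2) - 1) / n_surveys
  rho_log <- rho * sqrt(exp(sigma^2) * (1 + v_f) - 1) / sigma
  if (abs(rho_log) > 1) {
    stop_ns("response_rho = ", rho, " is unachievable with abundance_sigma = ",
            sigma, " (needs |log-scale correlation| = ", round(abs(rho_log), 3),
            " > 1); lower abundance_sigma or |response_rho|")
  }
  rho_log
}

#' Simulate an assemblage with known niche structure
#'
#' Per dimension, species are assigned to adaptive peaks (multinomial, every
#' peak occupied at least once); trait values are the peak centre plus
#' isotropic Gaussian noise plus a shared latent gradient component. Monthly
#' abundances are lognormal with a calibrated log-scale correlation so that
#' the natural-scale correlation between the latent gradient and mean
#' abundance equals `response_rho` in expectation. Fully reproducible from
#' `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return An object of class `synthetic_assemblage`: `assemblage`
#'   (passes validation as-is), `true_groups` (species x dimension integer
#'   matrix of peak labels), `gradient` (named latent-axis values),
#'   `response` (a `response_table`), `config`.
#' @export
simulate_assemblage <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_species
    ids <- sprintf("sp%03d", seq_len(n))
    g <- stats::rnorm(n)
    names(g) <- ids

    tables <- list()
    truth <- matrix(NA_integer_, n, length(cfg$dimensions),
                    dimnames = list(ids, cfg$dimensions))
    for (d in seq_along(cfg$dimensions)) {
      k <- cfg$n_groups[d]; p <- cfg$n_traits[d]
      lab <- sample(c(seq_len(k), sample.int(k, n - k, replace = TRUE)))
      peaks <- place_peaks(k, p, cfg$peak_separation * cfg$noise_sd)
      v <- stats::rnorm(p); v <- v / sqrt(sum(v^2))
      X <- peaks[lab, , drop = FALSE] +
        cfg$noise_sd * matrix(stats::rnorm(n * p), n, p) +
        cfg$gradient_strength * cfg$noise_sd * outer(g, v)
      dimnames(X) <- list(ids, sprintf("%s_t%d", cfg$dimensions[d], seq_len(p)))
      tables[[d]] <- trait_matrix(X, cfg$dimensions[d])
      truth[, d] <- lab
    }

    rho_log <- calibrate_rho_log(cfg$response_rho, cfg$abundance_sigma,
                                 cfg$survey_sigma, cfg$n_surveys)
    L <- rho_log * g + sqrt(1 - rho_log^2) * stats::rnorm(n)
    A <- exp(cfg$abundance_sigma * L)
    M <- A * exp(cfg$survey_sigma *
                   matrix(stats::rnorm(n * cfg$n_surveys), n, cfg$n_surveys) -
                   cfg$survey_sigma^2 / 2)
    dimnames(M) <- list(ids, sprintf("m%02d", seq_len(cfg$n_surveys)))

    structure(
      list(assemblage = assemblage(tables), true_groups = truth,
           gradient = g, response = compute_response_stats(M), config = cfg),
      class = "synthetic_assemblage"
    )
  })
}

#' @export
print.synthetic_assemblage <- function(x, ...) {
  cat(sprintf("<synthetic_assemblage> seed %d, planted rho = %.2f\n",
              x$config$seed, x$config$response_rho))
  print(x$assemblage)
  invisible(x)
}

#' Simulate a phylogeny with trait evolution toward adaptive peaks
#'
#' Generates a pure-birth topology and evolves multivariate traits along its
#' branches as Brownian motion plus Ornstein-Uhlenbeck attraction toward a
#' lineage-assigned peak. Peak assignments switch with probability
#' `switch_prob` per branch, so distant clades can share a peak — the
#' convergence scenario a niche projection should reveal (tips clustering in
#' niche space by peak, not by clade). With `attraction = 0` the process is
#' plain Brownian motion.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer seed.
#' @param n_traits trait-space dimensionality (default 2).
#' @param n_peaks number of adaptive peaks.
#' @param attraction OU pull toward the assigned peak (per unit time; 0 = BM).
#' @param sigma Brownian rate (SD per unit sqrt-time).
#' @param peak_separation distance between peaks in units of `sigma`.
#' @param switch_prob per-branch probability of switching peak.
#' @return An object of class `synthetic_phylogeny`: `tree` (`ape::phylo`,
#'   tips `t001`, ...), `tip_traits`, `tip_peaks`, `node_peaks`.
#' @export
simulate_phylogeny <- function(n_tips, seed = 1L, n_traits = 2L, n_peaks = 2L,
                               attraction = 1, sigma = 1, peak_separation = 6,
                               switch_prob = 0.15) {
  if (n_tips < 2L) stop_ns("n_tips must be >= 2")
  with_seed(seed, {
    phy <- ape::rphylo(n_tips, birth = 1, death = 0)
    phy$tip.label <- sprintf("t%03d", seq_len(n_tips))
    phy <- ape::reorder.phylo(phy, "cladewise")
    peaks <- place_peaks(n_peaks, n_traits, peak_separation * sigma)
    ntot <- n_tips + phy$Nnode
    state <- matrix(NA_real_, ntot, n_traits)
    peak_of <- integer(ntot)
    root <- n_tips + 1L
    peak_of[root] <- sample.int(n_peaks, 1L)
    state[root, ] <- peaks[peak_of[root], ]
    for (e in seq_len(nrow(phy$edge))) {
      par <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
      t_ <- phy$edge.length[e]
      peak_of[ch] <- if (stats::runif(1L) < switch_prob) {
        sample.int(n_peaks, 1L)
      } else {
        peak_of[par]
      }
      theta <- peaks[peak_of[ch], ]
      if (attraction > 0) {
        damp <- exp(-attraction * t_)
        vt <- sigma^2 * (1 - exp(-2 * attraction * t_)) / (2 * attraction)
      } else {
        damp <- 1
        vt <- sigma^2 * t_
      }
      state[ch, ] <- theta + (state[par, ] - theta) * damp +
        stats::rnorm(n_traits, sd = sqrt(vt))
    }
    tip_traits <- state[seq_len(n_tips), , drop = FALSE]
    dimnames(tip_traits) <- list(phy$tip.label, sprintf("trait_%d", seq_len(n_traits)))
    structure(
      list(tree = phy, tip_traits = tip_traits,
           tip_peaks = stats::setNames(peak_of[seq_len(n_tips)], phy$tip.label),
           node_peaks = peak_of),
      class = "synthetic_phylogeny"
    )
  })
}

#' @export
print.synthetic_phylogeny <- function(x, ...) {
  cat(sprintf("<synthetic_phylogeny> %d tips, %d peaks\n",
              length(x$tree$tip.label), length(unique(x$tip_peaks))))
  invisible(x)
}
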