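mk_groups <- function(species, ...) {
  lapply(list(...), function(v) setNames(as.integer(v), species))
}

test_that("assign_niche_codes builds ordered tuples in hierarchy order", {
  sp <- c("sp_a", "sp_b", "sp_c")
  g <- mk_groups(sp, habitat = c(2, 1, 1), trophic = c(1, 3, 1),
                 defence = c(1, 2, 1))
  codes <- assign_niche_codes(g)
  expect_identical(colnames(codes), c("habitat", "trophic", "defence"))
  expect_equal(unname(codes["sp_a", ]), c(2L, 1L, 1L))
  expect_identical(format_niche_codes(codes)[["sp_b"]], "1,3,2")
  expect_identical(format_niche_codes(codes, "prefixed")[["sp_b"]], "H1.T3.D2")

  # all single-leaf trees: everyone coded (1,1,...)
  g1 <- mk_groups(sp, habitat = c(1, 1, 1), trophic = c(1, 1, 1))
  expect_true(all(assign_niche_codes(g1) == 1L))

  # explicit hierarchy reordering permutes tuples consistently
  codes2 <- assign_niche_codes(g, hierarchy_order = c("defence", "habitat", "trophic"))
  expect_equal(unname(codes2["sp_a", ]), c(1L, 2L, 1L))

  g_bad <- g
  g_bad$trophic <- g_bad$trophic[-1]
  expect_error(assign_niche_codes(g_bad), "missing from dimension 'trophic'")
})

test_that("enumerate_niche_space counts and lists codes lexicographically", {
  e <- enumerate_niche_space(c(habitat = 4, life_history = 5, trophic = 6,
                               defence = 2, metabolic = 6))
  expect_equal(e$potential, 1440)
  expect_equal(nrow(e$codes), 1440)

  expect_equal(enumerate_niche_space(c(1, 1, 1, 1, 1))$potential, 1)

  e2 <- enumerate_niche_space(c(a = 2, b = 3))
  expect_equal(e2$potential, 6)
  expect_equal(unname(e2$codes),
               rbind(c(1, 1), c(1, 2), c(1, 3), c(2, 1), c(2, 2), c(2, 3)))

  expect_error(enumerate_niche_space(c(2, 0)), ">= 1")
  expect_null(enumerate_niche_space(c(1000, 1000))$codes)  # above cap
})

test_that("occupancy maps species onto the niche space", {
  sp <- sprintf("sp%d", 1:5)
  g <- mk_groups(sp, habitat = c(1, 1, 2, 2, 1), trophic = c(1, 1, 2, 3, 2))
  codes <- assign_niche_codes(g)
  occ <- occupancy(codes, c(habitat = 2, trophic = 3))
  expect_equal(occ$potential, 6)
  expect_equal(occ$n_occupied, 4)          # 5 species, one shared code
  expect_equal(occ$vacant_count, 2)
  expect_length(occ$multi_occupied, 1)
  expect_identical(occ$multi_occupied[["1,1"]], c("sp1", "sp2"))
  expect_equal(sum(lengths(occ$occupied)), 5)

  # identical codes for everyone: one occupied niche
  g1 <- mk_groups(sp, habitat = rep(1, 5), trophic = rep(2, 5))
  expect_equal(occupancy(assign_niche_codes(g1))$n_occupied, 1)

  # species input order never matters
  occ2 <- occupancy(codes[rev(seq_len(nrow(codes))), , drop = FALSE], c(2, 3))
  expect_identical(occ2$occupied, occ$occupied)
})

test_that("hierarchy order changes codes but never occupancy accounting", {
  sim <- simulate_assemblage(sim_config(seed = 31))
  ords <- lapply(sim$assemblage$tables, ordinate_dimension)
  groups <- lapply(names(ords), function(d) {
    tr <- niche_tree(sim$assemblage$tables[[d]], ords[[d]])
    assign_groups(tr, sim$assemblage$tables[[d]]$values)
  })
  names(groups) <- names(ords)
  a <- occupancy(assign_niche_codes(groups))
  b <- occupancy(assign_niche_codes(groups, rev(names(groups))))
  expect_equal(a$potential, b$potential)
  expect_equal(a$n_occupied, b$n_occupied)
  expect_equal(a$vacant_count, b$vacant_count)
})

test_that("build_composite_tree nests dimensions with occupancy annotations", {
  sp <- sprintf("sp%d", 1:5)
  g <- mk_groups(sp, habitat = c(1, 1, 2, 2, 1), trophic = c(1, 1, 2, 3, 2))
  occ <- occupancy(assign_niche_codes(g), c(habitat = 2, trophic = 3))
  ct <- build_composite_tree(c(habitat = 2, trophic = 3), occ)
  expect_equal(ct$n_tips, 6)
  tips <- nichescheme:::composite_tips(ct$root)
  expect_length(tips, 6)
  expect_equal(sum(vapply(tips, function(t) t$occupied, logical(1))), 4)
  # every species at exactly one occupied tip
  all_sp <- sort(unlist(lapply(tips, function(t) t$species)))
  expect_identical(all_sp, sort(sp))
  # depth 2: every tip code has two entries
  expect_true(all(vapply(tips, function(t) length(t$code), integer(1)) == 2L))

  # single-leaf everything: one tip
  expect_equal(build_composite_tree(c(habitat = 1, trophic = 1))$n_tips, 1)

  expect_error(build_composite_tree(integer()), "named")
})

test_that("composite exports carry labels, species and vacancy flags", {
  sp <- c("sp1", "sp2")
  g <- mk_groups(sp, habitat = c(1, 2), trophic = c(1, 2))
  occ <- occupancy(assign_niche_codes(g), c(habitat = 2, trophic = 2))
  ct <- build_composite_tree(c(habitat = 2, trophic = 2), occ)

  nwk <- composite_newick(ct, include_vacant = TRUE)
  expect_match(nwk, ";$")
  expect_match(nwk, "H1.T1|sp1", fixed = TRUE)
  expect_equal(lengths(regmatches(nwk, gregexpr("VACANT", nwk))), 2)
  # suppressed vacants: parseable by ape and only occupied tips remain
  nwk2 <- composite_newick(ct)
  phy <- ape::read.tree(text = nwk2)
  expect_equal(length(phy$tip.label), 2)

  out <- composite_outline(ct, include_vacant = TRUE)
  expect_true(any(grepl("H2.T2: sp2", out, fixed = TRUE)))
  expect_true(any(grepl("VACANT", out)))
})
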