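test_that("the bundled synthetic database loads and validates", {
  db <- synthetic_compound_db()
  expect_s3_class(db, "compound_db")
  expect_gt(nrow(db$compounds), 30)
  expect_true(all(db$compounds$mass > 0))
  expect_true(all(unlist(db$members) %in% db$compounds$compound_id))
})

test_that("malformed databases are rejected", {
  cmp <- tibble::tibble(compound_id = "c1", name = "x", mass = 100)
  pw_bad <- tibble::tibble(pathway_id = "p1", name = "p", members = "c1,c9")
  expect_error(compound_db(cmp, pw_bad), "missing from compound table")
  cmp_bad <- tibble::tibble(compound_id = "c1", name = "x", mass = -5)
  pw <- tibble::tibble(pathway_id = "p1", name = "p", members = "c1")
  expect_error(compound_db(cmp_bad, pw), "positive")
})

test_that("protonated glutamine is annotated within 1 ppm", {
  db <- synthetic_compound_db()
  ann <- annotate(c(gln = 147.0764), db, tol_ppm = 10)
  hit <- ann[ann$compound_id == db$compounds$compound_id[
    db$compounds$name == "glutamine"
  ], ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$adduct, "M+H")
  expect_lt(abs(hit$ppm_error), 1)
})

test_that("annotation respects the tolerance and empty inputs", {
  db <- synthetic_compound_db()
  none <- annotate(90.5, db, tol_ppm = 10)
  expect_equal(nrow(none), 0)
  # tol 0 keeps only exact matches
  exact_mz <- db$compounds$mass[1] + 1.007276
  ann0 <- annotate(exact_mz, db, tol_ppm = 0)
  expect_equal(ann0$compound_id, db$compounds$compound_id[1])
  ann_off <- annotate(exact_mz + 1e-4, db, tol_ppm = 0)
  expect_equal(nrow(ann_off), 0)
  empty_db <- compound_db(
    tibble::tibble(compound_id = character(), name = character(), mass = numeric()),
    tibble::tibble(pathway_id = character(), name = character(), members = character())
  )
  expect_error(annotate(100, empty_db), "empty")
})

fake_results <- function(n_per_col = 30) {
  tibble::tibble(
    feature_id = sprintf("f%03d", seq_len(2 * n_per_col)),
    column = rep(c("AE", "C18"), each = n_per_col),
    factor = "age",
    p = rep(seq(0.001, 0.9, length.out = n_per_col), 2),
    estimate = rep(c(1, -1), n_per_col),
    significant = TRUE,
    direction = NA_character_
  )
}

test_that("top-list selection orders by p, splits by sign, breaks ties by id", {
  res <- fake_results(30)
  top <- select_top(res, "age", n = 5, sign = "pos")
  expect_equal(nrow(top), 10) # 5 per column
  for (cl in c("AE", "C18")) {
    sub <- top[top$column == cl, ]
    expect_true(all(sub$estimate > 0))
    rest <- res[res$column == cl & res$estimate > 0 &
                  !(res$feature_id %in% sub$feature_id), ]
    expect_true(max(sub$p) <= min(rest$p))
  }
  expect_warning(select_top(res, "age", n = 500, sign = "neg"), "fewer than")

  # ties at the cutoff break deterministically by feature id
  tied <- res
  tied$p <- 0.5
  t1 <- select_top(tied, "age", n = 4, sign = "all")
  expect_equal(t1$feature_id[t1$column == "AE"], sprintf("f%03d", 1:4))
})

test_that("empirical enrichment p-values are bounded, monotone and reproducible", {
  set.seed(14)
  universe <- tibble::tibble(
    feature_id = sprintf("u%03d", 1:200),
    mz = runif(200, 90, 600)
  )
  db <- compound_db(
    tibble::tibble(
      compound_id = c("c1", "c2", "c3", "c4"),
      name = paste0("syn", 1:4),
      mass = universe$mz[c(1, 2, 3, 4)] - 1.007276
    ),
    tibble::tibble(
      pathway_id = c("pA", "pB"),
      name = c("planted", "empty"),
      members = c("c1,c2,c3", "c4")
    )
  )
  sel_hit <- universe$feature_id[1:3] # all annotated to pA
  r_hit <- enrich(sel_hit, universe, db, n_perm = 199, seed = 3)
  expect_true(all(r_hit$p_emp >= 1 / 200 & r_hit$p_emp <= 1))
  expect_lt(r_hit$p_emp[r_hit$pathway_id == "pA"], 0.05)

  sel_miss <- universe$feature_id[100:102] # no annotation
  r_miss <- enrich(sel_miss, universe, db, n_perm = 199, seed = 3)
  expect_equal(r_miss$observed[r_miss$pathway_id == "pA"], 0L)
  expect_equal(r_miss$p_emp[r_miss$pathway_id == "pA"], 1, tolerance = 1 / 200)

  # monotone: larger observed overlap cannot raise the empirical p
  expect_lt(
    r_hit$p_emp[r_hit$pathway_id == "pA"],
    r_miss$p_emp[r_miss$pathway_id == "pA"]
  )
  r_rep <- enrich(sel_hit, universe, db, n_perm = 199, seed = 3)
  expect_identical(r_hit$p_emp, r_rep$p_emp)

  expect_warning(enrich(sel_hit, universe, db, n_perm = 50, seed = 1), "coarse")
  expect_error(enrich("nope", universe, db), "part of the universe")
})

test_that("enrichment with an empty pathway set returns an empty result", {
  universe <- tibble::tibble(feature_id = c("a", "b"), mz = c(100, 200))
  db <- compound_db(
    tibble::tibble(compound_id = "c1", name = "x", mass = 150),
    tibble::tibble(pathway_id = character(), name = character(), members = character())
  )
  out <- enrich("a", universe, db, n_perm = 199)
  expect_s3_class(out, "enrichment_result")
  expect_equal(nrow(out), 0)
})

test_that("heritable-feature enrichment warns on short screens and runs per column", {
  her <- tibble::tibble(
    feature_id = sprintf("u%03d", 1:40),
    column = rep(c("AE", "C18"), each = 20),
    sigma2_between = 1, sigma2_within = 1,
    t = runif(40, 0, 0.4),
    rank = rep(1:20, 2), heritable = TRUE, top150 = TRUE
  )
  class(her) <- c("heritability_result", class(her))
  universe <- tibble::tibble(
    feature_id = sprintf("u%03d", 1:40),
    column = rep(c("AE", "C18"), each = 20),
    mz = runif(40, 90, 600)
  )
  db <- compound_db(
    tibble::tibble(compound_id = "c1", name = "x",
                   mass = universe$mz[1] - 1.007276),
    tibble::tibble(pathway_id = "p1", name = "p", members = "c1")
  )
  w <- capture_warnings(out <- heritable_enrichment(her, universe, db, n_perm = 199))
  expect_true(any(grepl("only", w))) # one short-screen warning per column
  expect_equal(sort(unique(out$column)), c("AE", "C18"))
})
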