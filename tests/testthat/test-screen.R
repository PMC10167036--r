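test_that("abundance filter keeps genes whose maximum clears the threshold", {
  m <- expression_matrix(rbind(a = c(50, 1), b = c(29.9, 10), c = c(30, 2)),
                         conditions = c("x", "y"))
  kept <- filter_by_abundance(m, 30)
  expect_identical(rownames(kept), c("a", "c"))
  expect_identical(rownames(filter_by_abundance(m, 0)), c("a", "b", "c"))
  # retained count is non-increasing in the threshold
  counts <- vapply(c(0, 10, 29.9, 30, 31),
                   function(th) nrow(filter_by_abundance(m, th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_warning(empty <- filter_by_abundance(m, 1e6), "every gene")
  expect_equal(nrow(empty), 0)
})

test_that("row standardization uses the population SD and drops constant rows", {
  expect_warning(
    std <- standardize_rows(rbind(a = c(0, 2), b = c(1, 1, 1, 1, 1)[1:2])),
    "constant")
  expect_equal(unname(std["a", ]), c(-1, 1))
  expect_identical(attr(std, "excluded"), "b")
  x <- matrix(rlnorm(50), 10, 5)
  std <- standardize_rows(x)
  expect_true(all(abs(rowMeans(std)) < 1e-12))
  expect_true(all(abs(sqrt(rowMeans(std^2)) - 1) < 1e-12))
})

test_that("core assignment respects the inclusive membership threshold and ties", {
  u <- rbind(g1 = c(0.71, 0.19, 0.10),
             g2 = c(0.69, 0.21, 0.10),
             g3 = c(1.00, 0.00, 0.00),
             g4 = c(0.45, 0.45, 0.10))
  asg <- core_assignments(fake_fcm(u), acore = 0.7)
  expect_equal(asg[["g1"]], 1)
  expect_true(is.na(asg[["g2"]]))
  expect_equal(asg[["g3"]], 1)
  expect_true(is.na(asg[["g4"]]))
  # tie at the argmax above the threshold goes to the lowest index
  asg2 <- core_assignments(fake_fcm(rbind(g = c(0.5, 0.5, 0))), acore = 0.4)
  expect_equal(asg2[["g"]], 1)
})

test_that("marker plurality selects clusters; ties and empties are flagged", {
  asg <- c(m1 = 1, m2 = 1, m3 = 1, d1 = 4, d2 = 4, d3 = 2, d4 = NA)
  sel <- select_pathway_clusters(asg, list(common = c("m1", "m2", "m3"),
                                           downstream = c("d1", "d2", "d3")))
  expect_equal(sel$common$clusters, 1)
  expect_equal(sel$downstream$clusters, 4)
  # 3-vs-2 split selects the plurality cluster
  maj <- select_pathway_clusters(asg, list(s = c("m1", "m2", "m3", "d1", "d2")))
  expect_equal(maj$s$clusters, 1)
  expect_false(maj$s$tied)
  # 2-vs-2 plurality tie returns both, flagged
  tie2 <- select_pathway_clusters(asg, list(s = c("d1", "d2", "m1", "m2")))
  expect_true(tie2$s$tied)
  expect_setequal(tie2$s$clusters, c(1, 4))
  # unassigned-only marker set selects nothing
  none <- select_pathway_clusters(asg, list(s = "d4"))
  expect_true(none$s$empty)
})

test_that("the full screen recovers planted candidates exactly at zero noise", {
  st <- synth_screen_study(n_genes = 1500, noise_cv = 0, seed = 4)
  tab <- run_screen(st$matrix, st$sequences, st$marker_sets,
                    screen_config(seed = 4), st$queries)
  pr <- screen_precision_recall(tab, st$candidate_ids)
  expect_equal(pr$precision, 1)
  expect_equal(pr$recall, 1)
  counts <- attr(tab, "stage_counts")
  expect_true(all(diff(unname(counts)) <= 0))
})

test_that("empty marker sets yield an empty candidate table with a warning", {
  st <- synth_screen_study(n_genes = 1500, noise_cv = 0, seed = 4)
  expect_warning(
    tab <- run_screen(st$matrix, st$sequences, list(), screen_config(seed = 4),
                      st$queries),
    "marker")
  expect_equal(sum(tab$candidate), 0)
})

test_that("candidate flags are consistent with the stagewise criteria", {
  st <- synth_screen_study(n_genes = 1500, noise_cv = 0.2, seed = 2)
  tab <- run_screen(st$matrix, st$sequences, st$marker_sets,
                    screen_config(seed = 2), st$queries)
  expect_true(all(!tab$candidate |
                    (tab$passes_abundance & tab$passes_cluster &
                       tab$passes_homology)))
  expect_true(all(is.na(tab$best_score) |
                    (tab$best_score >= 0)))
  scored <- !is.na(tab$best_score)
  expect_true(all(tab$passes_homology[scored] ==
                    (tab$best_score[scored] >= 50)))
})
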