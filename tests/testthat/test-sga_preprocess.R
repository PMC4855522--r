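test_that("call_valid_sga applies mutation and CNV-concordance rules with inclusive z", {
  sga <- suppressWarnings(call_valid_sga(tiny_cohort()))
  expect_identical(sga$G1, "T1")                  # mutation alone is valid
  expect_identical(sga$G2, "T2")                  # z = 1.64 valid, 1.50 not
  expect_identical(sga$G3, "T4")                  # z = -1.70 with GISTIC -2
  expect_false("G4" %in% names(sga))              # zero-sd background skipped
  expect_warning(call_valid_sga(tiny_cohort()), "background")
})

test_that("filter_rare_genes drops genes with no more than five event tumors", {
  sga <- structure(list(keep6 = sprintf("T%d", 1:6),
                        drop5 = sprintf("T%d", 1:5),
                        drop1 = "T1"),
                   class = "valid_sga")
  filtered <- filter_rare_genes(sga)
  expect_identical(names(filtered), "keep6")
  expect_length(filter_rare_genes(structure(list(), class = "valid_sga")), 0)
})

test_that("fold_changes uses the normal median with a pseudocount", {
  expr <- matrix(c(30, 10, 19,   10, 10, 10,   10, 10, 10),
                 nrow = 3, byrow = FALSE,
                 dimnames = list(c("gA", "gB", "gC"),
                                 c("T1", "N1", "N2")))
  ann <- data.frame(sample = c("T1", "N1", "N2"),
                    type = c("tumor", "normal", "normal"))
  f0 <- fold_changes(expr, ann, eps = 0)
  expect_equal(unname(f0[, "T1"]), c(3, 1, 1.9))  # 30/10, 10/10, 19/10
  f1 <- fold_changes(expr, ann, eps = 1)
  expect_equal(f1["gA", "T1"], 31 / 11)
  # log2 input is unlogged first
  fl <- fold_changes(log2(expr), ann, eps = 0, log2_input = TRUE)
  expect_equal(unname(fl[, "T1"]), c(3, 1, 1.9))
})

test_that("partition_tumors enforces the strict 75 % and inclusive 50 % rules", {
  # 4 signature genes x 6 tumors with controlled fold changes
  folds <- matrix(1, 4, 6, dimnames = list(sprintf("g%d", 1:4),
                                           sprintf("T%d", 1:6)))
  folds[, "T1"] <- 3                      # 4/4 up -> S_p
  folds[1:3, "T2"] <- 3                   # 3/4 = 75 %, not > 75 % -> not S_p
  folds[, "T3"] <- c(1.5, 1.5, 2.5, 2.5)  # 2/4 = 50 % under twofold -> S_n
  folds[, "T4"] <- 1 / 3                  # 4/4 down -> S_p (down)
  folds[, "T5"] <- c(2.5, 2.5, 2.5, 1.5)  # 1/4 under twofold -> unassigned
  folds[, "T6"] <- 1
  part <- partition_tumors(rownames(folds), folds, "sig", min_sp = 0)
  expect_identical(part$status, "rejected")  # up and down groups comparable
  part2 <- partition_tumors(rownames(folds), folds[, -4], "sig", min_sp = 0)
  expect_identical(part2$S_p, "T1")
  expect_identical(part2$direction[["T1"]], "up")
  expect_true(all(c("T3", "T6") %in% part2$S_n))
  expect_false("T2" %in% part2$S_p)
  expect_false("T5" %in% c(part2$S_p, part2$S_n))
  expect_error(partition_tumors(character(0), folds), "empty signature")
})

test_that("sub-group and |S_p| > 30 acceptance rules fire at their boundaries", {
  n_up <- 100; n_down <- 9
  tumors <- sprintf("T%03d", seq_len(n_up + n_down + 10))
  folds <- matrix(1, 2, length(tumors),
                  dimnames = list(c("g1", "g2"), tumors))
  folds[, 1:n_up] <- 3
  folds[, n_up + seq_len(n_down)] <- 1 / 3
  part <- partition_tumors(c("g1", "g2"), folds, "s")
  expect_identical(part$status, "accepted")   # 9 < 10 % of 100: drop smaller
  expect_length(part$S_p, n_up)
  expect_true(all(part$direction == "up"))

  folds2 <- folds
  folds2[, n_up + 10] <- 1 / 3                # now 10/100: reject signature
  part2 <- partition_tumors(c("g1", "g2"), folds2, "s")
  expect_identical(part2$status, "rejected")

  # exactly 30 perturbed tumors is not enough
  folds3 <- matrix(1, 2, 40, dimnames = list(c("g1", "g2"), sprintf("T%d", 1:40)))
  folds3[, 1:30] <- 3
  part3 <- partition_tumors(c("g1", "g2"), folds3, "s")
  expect_identical(part3$status, "rejected")
  expect_match(part3$reason, "30")
  folds3[, 31] <- 3
  expect_identical(partition_tumors(c("g1", "g2"), folds3, "s")$status,
                   "accepted")
})

test_that("compute_weights is the hypergeometric upper tail and ranks informative genes first", {
  part <- wmemcover:::new_partition(
    "s", sprintf("P%02d", 1:30), sprintf("Q%02d", 1:70),
    stats::setNames(rep("up", 30), sprintf("P%02d", 1:30)),
    "accepted", NA_character_)
  sga <- structure(list(
    g1 = c(sprintf("P%02d", 1:10), sprintf("Q%02d", 1:2)),    # 10 of 12 in S_p
    g2 = c(sprintf("P%02d", 1:10), sprintf("Q%02d", 1:20)),   # 10 of 30 in S_p
    g0 = sprintf("Q%02d", 1:5)),                              # none in S_p
    class = "valid_sga")
  w <- compute_weights(sga, part)
  wmap <- stats::setNames(w$weight, w$gene)
  expect_lt(wmap[["g1"]], wmap[["g2"]])
  expect_equal(wmap[["g1"]], hyper_tail_oracle(10, 30, 100, 12))
  expect_equal(wmap[["g2"]], hyper_tail_oracle(10, 30, 100, 30))
  expect_identical(wmap[["g0"]], 1)          # k = 0 -> P(X >= 0) = 1
  expect_identical(w$gene[1], "g1")          # sorted ascending by weight
})

test_that("weights are monotone in S_p hits and in total events", {
  part <- wmemcover:::new_partition(
    "s", sprintf("P%02d", 1:20), sprintf("Q%02d", 1:40),
    stats::setNames(rep("up", 20), sprintf("P%02d", 1:20)),
    "accepted", NA_character_)
  weight_of <- function(k_p, n_g) {
    sga <- structure(list(g = c(sprintf("P%02d", seq_len(k_p)),
                                sprintf("Q%02d", seq_len(n_g - k_p)))),
                     class = "valid_sga")
    compute_weights(sga, part)$weight
  }
  w_by_k <- vapply(0:10, weight_of, 0, n_g = 10)
  expect_true(all(diff(w_by_k) <= 1e-15))    # non-increasing in k_g
  w_by_n <- vapply(8:30, function(n) weight_of(8, n), 0)
  expect_true(all(diff(w_by_n) >= -1e-15))   # non-decreasing in n_g
  # all-in-S_p certain event
  part_small <- wmemcover:::new_partition(
    "s", c("P1", "P2"), character(0),
    stats::setNames(rep("up", 2), c("P1", "P2")), "accepted", NA_character_)
  sga_all <- structure(list(g = c("P1", "P2")), class = "valid_sga")
  expect_identical(compute_weights(sga_all, part_small)$weight, 1)
})

test_that("select_candidates applies the strict 0.2 bound and top-200 truncation", {
  w <- data.frame(gene = sprintf("G%03d", 1:250),
                  k_p = 1L, k_n = 0L, n_g = 1L,
                  weight = seq(0.001, 0.199, length.out = 250))
  expect_length(select_candidates(w), 200)
  expect_length(select_candidates(w[1:150, ]), 150)
  w2 <- data.frame(gene = c("A", "B"), k_p = 1L, k_n = 0L, n_g = 1L,
                   weight = c(0.2, 0.19))
  expect_identical(select_candidates(w2), "B")   # exactly 0.2 is excluded
})

test_that("build_cover_instance restricts candidate sets to S_p", {
  part <- wmemcover:::new_partition(
    "s", sprintf("T%d", 1:5), sprintf("S%d", 1:50),
    stats::setNames(rep("up", 5), sprintf("T%d", 1:5)),
    "accepted", NA_character_)
  sga <- structure(list(
    g1 = c("T1", "T2"), g2 = c("T2", "T3", "T4"), g3 = c("T2", "T5"),
    g4 = c("S1", "S2")), class = "valid_sga")
  w <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                  k_p = 0L, k_n = 0L, n_g = 0L,
                  weight = c(0.1, 0.02, 0.3, 0.15))
  inst <- build_cover_instance(part, sga, w, c("g1", "g2", "g3", "g4"))
  expect_identical(inst$universe, sprintf("T%d", 1:5))
  expect_identical(names(inst$sets), c("g1", "g2", "g3"))  # g4 restricted empty
  expect_identical(inst$sets$g2, c("T2", "T3", "T4"))
  expect_identical(wmem_solve(inst)$solution$chosen, "g2")
  empty <- build_cover_instance(part, sga, w, character(0))
  expect_length(empty$sets, 0)
})

test_that("the pipeline is idempotent on identical inputs", {
  sim <- small_cohort()
  r1 <- preprocess_signature(sim$cohort, sim$signatures[[1]]$genes, "s")
  r2 <- preprocess_signature(sim$cohort, sim$signatures[[1]]$genes, "s")
  expect_identical(r1$partition[names(r1$partition) != "reason"],
                   r2$partition[names(r2$partition) != "reason"])
  expect_identical(r1$weights, r2$weights)
  expect_identical(r1$instance, r2$instance)
})
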