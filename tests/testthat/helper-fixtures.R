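# Shared fixtures and checkers, all built in code.

# The three-gene toy instance: every pair of sets shares T2, so only
# singleton families are feasible and the largest set wins on coverage.
toy_instance <- function(w = c(g1 = 0.1, g2 = 0.02, g3 = 0.3)) {
  cover_instance(
    sets = list(g1 = c("T1", "T2"),
                g2 = c("T2", "T3", "T4"),
                g3 = c("T2", "T5")),
    weights = w)
}

path_instance <- function(ids = c("A", "B", "C"), w = rep(0, length(ids))) {
  # consecutive sets share one element: A={1,2}, B={2,3}, C={3,4}, ...
  sets <- lapply(seq_along(ids), function(i) as.character(c(i, i + 1)))
  names(sets) <- ids
  cover_instance(sets, w)
}

ring_instance <- function(w = c(A = 1, B = 2, C = 3)) {
  cover_instance(list(A = c("1", "2"), B = c("2", "3"), C = c("3", "1")), w)
}

# Independent validity check: chosen sets exist, are pairwise disjoint, and
# the reported coverage/weight match direct recomputation.
expect_valid_solution <- function(instance, solution) {
  inst <- normalize_instance(instance)
  expect_true(all(solution$chosen %in% names(inst$sets)))
  elems <- unlist(inst$sets[solution$chosen], use.names = FALSE)
  expect_false(anyDuplicated(elems) > 0)
  expect_identical(solution$coverage, length(elems))
  expect_equal(solution$weight,
               sum(inst$weights[sort(solution$chosen, method = "radix")]))
}

expect_same_solution <- function(a, b) {
  expect_identical(a$chosen, b$chosen)
  expect_identical(a$coverage, b$coverage)
  expect_equal(a$weight, b$weight, tolerance = 1e-12)
}

# Direct hypergeometric upper tail by explicit summation (oracle independent
# of stats::phyper): P(X >= k) with n draws, K successes among N.
hyper_tail_oracle <- function(k, K, N, n) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Small noiseless cohort shared by preprocessing tests (fast to generate).
small_cohort <- function(seed = 7, passenger_rate = 0.08, ...) {
  synthetic_cohort(n_tumors = 120, n_normals = 10, n_genes = 80,
                   signature_size = 6, n_drivers = 3,
                   passenger_rate = passenger_rate,
                   fold_effect = 3, noise_sd = 0, seed = seed, ...)
}

# A tiny hand-built cohort exercising each valid-SGA rule.  Backgrounds are
# chosen so mean = 0 and sd = 1 hold exactly in floating point, making the
# z = 1.64 boundary exact (GISTIC +/-1 tumors are excluded from the GISTIC-0
# background, which also checks that +/-1 calls are ignored).
tiny_cohort <- function() {
  tumors <- sprintf("T%d", 1:6)
  normals <- c("N1", "N2", "N3")
  genes <- c("G1", "G2", "G3", "G4")
  mutation <- matrix(0L, 4, 6, dimnames = list(genes, tumors))
  mutation["G1", "T1"] <- 1L
  gistic <- matrix(0L, 4, 6, dimnames = list(genes, tumors))
  gistic["G2", c("T2", "T3")] <- 2L
  gistic["G2", "T1"] <- 1L            # ignored level, excluded from background
  gistic["G3", "T4"] <- -2L
  gistic["G4", "T5"] <- 2L            # G4 background is constant -> CNV skipped
  expr <- matrix(0, 4, 9, dimnames = list(genes, c(tumors, normals)))
  expr["G2", c("T4", "T5", "T6")] <- c(-1, 0, 1)   # mean 0, sd 1 exactly
  expr["G2", "T2"] <- 1.64            # z = 1.64 exactly -> valid (inclusive)
  expr["G2", "T3"] <- 1.50            # z = 1.50 -> not valid
  # G3 background T1,T2,T3,T5,T6: mean 0, sd 1 exactly
  expr["G3", c("T1", "T2", "T3", "T5", "T6")] <- c(-1, -1, 0, 1, 1)
  expr["G3", "T4"] <- -1.70           # z = -1.70 with GISTIC -2 -> valid
  ann <- data.frame(sample = c(tumors, normals),
                    type = rep(c("tumor", "normal"), c(6, 3)))
  cohort_data(mutation, gistic, expr, ann)
}
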