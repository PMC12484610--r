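test_that("causal_network validates signs, duplicates and universe", {
  net <- tiny_network()
  expect_equal(nrow(net$edges), 5)
  expect_equal(length(net$universe), 6)
  # string signs are accepted
  net2 <- causal_network(data.frame(regulator_id = "R1",
                                    target_gene = c("G1", "G2"),
                                    sign = c("activation", "inhibition"),
                                    stringsAsFactors = FALSE))
  expect_equal(net2$edges$sign, c(1L, -1L))
  # duplicate pairs (even with conflicting signs) are rejected
  expect_error(causal_network(data.frame(
    regulator_id = c("R1", "R1"), target_gene = c("G1", "G1"),
    sign = c(1L, -1L), stringsAsFactors = FALSE)), "duplicate")
  expect_error(causal_network(data.frame(
    regulator_id = "R1", target_gene = "GX", sign = 1L,
    stringsAsFactors = FALSE), universe = c("G1", "G2")), "universe")
})

test_that("overlap p-value matches the hypergeometric worked example", {
  # universe 10, regulator targets 4, observed 5, overlap 4:
  # P(X >= 4) = choose(4,4) choose(6,1) / choose(10,5) = 6/252
  net <- causal_network(data.frame(
    regulator_id = "R1", target_gene = paste0("G", 1:4), sign = 1L,
    stringsAsFactors = FALSE), universe = paste0("G", 1:10))
  p <- overlap_pvalue(net, paste0("G", 1:5))
  expect_equal(unname(p), 6 / 252)
  # zero overlap gives p = 1
  p0 <- overlap_pvalue(net, paste0("G", 7:9))
  expect_equal(unname(p0), 1)
  expect_error(overlap_pvalue(net, paste0("G", 1:5), universe_size = 3),
               "smaller")
})

test_that("overlap p-value equals brute-force enumeration on small universes", {
  set.seed(6)
  for (trial in 1:5) {
    u_size <- sample(8:12, 1)
    universe <- paste0("G", seq_len(u_size))
    targets <- sample(universe, sample(2:5, 1))
    observed <- sample(universe, sample(2:6, 1))
    net <- causal_network(data.frame(
      regulator_id = "R1", target_gene = targets, sign = 1L,
      stringsAsFactors = FALSE), universe = universe)
    got <- unname(overlap_pvalue(net, observed))
    k_obs <- length(intersect(targets, observed))
    subsets <- utils::combn(universe, length(observed))
    overlaps <- apply(subsets, 2, function(s) length(intersect(s, targets)))
    expect_equal(got, mean(overlaps >= k_obs), tolerance = 1e-12)
  }
})

test_that("activation z-score matches its printed worked examples", {
  # 6 consistent edges: z = 6/sqrt(6) = 2.449
  net6 <- causal_network(data.frame(
    regulator_id = "R", target_gene = paste0("G", 1:6), sign = 1L,
    stringsAsFactors = FALSE))
  obs6 <- data.frame(gene = paste0("G", 1:6), direction = 1L,
                     stringsAsFactors = FALSE)
  z6 <- activation_z(net6, obs6, "R")
  expect_equal(round(z6$z, 3), 2.449)
  expect_equal(z6$n_plus, 6)
  # 4 inconsistent edges: z = -2.000
  net4 <- causal_network(data.frame(
    regulator_id = "R", target_gene = paste0("G", 1:4), sign = 1L,
    stringsAsFactors = FALSE))
  obs4 <- data.frame(gene = paste0("G", 1:4), direction = -1L,
                     stringsAsFactors = FALSE)
  expect_equal(activation_z(net4, obs4, "R")$z, -2)
  # balanced evidence: z = 0
  obs_bal <- data.frame(gene = paste0("G", 1:4),
                        direction = c(1L, 1L, -1L, -1L),
                        stringsAsFactors = FALSE)
  expect_equal(activation_z(net4, obs_bal, "R")$z, 0)
  expect_error(activation_z(net4, obs4, "NOPE"), "unknown regulator")
})

test_that("z-score structural invariants hold on random instances", {
  set.seed(10)
  for (s in 1:10) {
    net <- simulate_network(network_sim_config(n_regulators = 5,
                                               n_genes = 30, seed = s))
    genes <- sample(net$universe, 15)
    obs <- data.frame(gene = genes,
                      direction = sample(c(-1L, 1L), 15, replace = TRUE),
                      stringsAsFactors = FALSE)
    flipped <- obs
    flipped$direction <- -obs$direction
    for (rg in unique(net$edges$regulator_id)) {
      sc <- activation_z(net, obs, rg)
      expect_lte(abs(sc$z), sqrt(max(sc$n, 1)) + 1e-12)
      if (sc$n > 0 && sc$n_minus == 0) expect_equal(sc$z, sqrt(sc$n))
      # flipping every observed direction negates z
      expect_equal(activation_z(net, flipped, rg)$z, -sc$z)
    }
  }
})

test_that("bias-corrected p matches exhaustive enumeration on 3 genes", {
  net <- causal_network(data.frame(
    regulator_id = "R", target_gene = c("G1", "G2", "G3"),
    sign = c(1L, 1L, -1L), stringsAsFactors = FALSE))
  obs <- data.frame(gene = c("G1", "G2", "G3"),
                    direction = c(1L, 1L, -1L), stringsAsFactors = FALSE)
  z_obs <- activation_z(net, obs, "R")$z
  # exact: all 3! direction reassignments (permutations of the multiset)
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  z_all <- apply(perms, 1, function(pp) {
    sum(c(1, 1, -1) * obs$direction[pp]) / sqrt(3)
  })
  exact <- mean(abs(z_all) >= abs(z_obs) - 1e-12)
  n_perm <- 2000
  got <- bias_corrected_p(net, obs, "R", n_perm = n_perm, seed = 5)
  expect_lt(abs(got - exact), 2 / sqrt(n_perm))
  # seeded: reproducible
  expect_identical(got, bias_corrected_p(net, obs, "R", n_perm = n_perm,
                                         seed = 5))
})

test_that("bias-corrected p is monotone in |z| and handles degenerate cases", {
  universe <- paste0("G", 1:12)
  obs <- data.frame(gene = universe,
                    direction = rep(c(1L, -1L), 6), stringsAsFactors = FALSE)
  consistent <- causal_network(data.frame(
    regulator_id = "R", target_gene = universe,
    sign = obs$direction, stringsAsFactors = FALSE), universe = universe)
  balanced <- causal_network(data.frame(
    regulator_id = "R", target_gene = universe,
    sign = c(obs$direction[1:6], -obs$direction[7:12]),
    stringsAsFactors = FALSE), universe = universe)
  p_hi <- bias_corrected_p(consistent, obs, "R", n_perm = 500, seed = 1)
  p_lo <- bias_corrected_p(balanced, obs, "R", n_perm = 500, seed = 1)
  expect_lt(p_hi, p_lo)
  expect_equal(p_lo, 1, tolerance = 0.05)  # z = 0: nothing is more extreme
  # flipping all observed directions leaves the permutation p unchanged
  flipped <- obs
  flipped$direction <- -obs$direction
  expect_equal(bias_corrected_p(consistent, flipped, "R", n_perm = 500,
                                seed = 1), p_hi)
  # regulator with no observed target
  net2 <- causal_network(data.frame(
    regulator_id = "R2", target_gene = "G99", sign = 1L,
    stringsAsFactors = FALSE), universe = c(universe, "G99"))
  expect_warning(p_na <- bias_corrected_p(net2, obs, "R2", n_perm = 500),
                 "no target")
  expect_equal(p_na, 1)
})

test_that("significance filter applies both thresholds inclusively on z", {
  scores <- data.frame(
    regulator_id = c("A", "B", "C", "D"),
    z = c(1.9, 2.000, 2.5, -2.2),
    p_bias_corrected = c(0.001, 0.0006, 0.02, 0.005),
    stringsAsFactors = FALSE)
  out <- filter_significant(scores)
  expect_setequal(out$regulator_id, c("B", "D"))  # A fails z, C fails p
  expect_equal(out$predicted_state[out$regulator_id == "B"], "activated")
  expect_equal(out$predicted_state[out$regulator_id == "D"], "inhibited")
})

test_that("mechanical-change predictions follow the sign algebra", {
  expect_equal(predict_mechanical_change(list(z = 2.4), "activate"),
               "increase")
  expect_equal(predict_mechanical_change(list(z = 2.4), "inhibit"),
               "decrease")
  # inhibiting a negative-z regulator is a double negation
  expect_equal(predict_mechanical_change(list(z = -2), "inhibit"),
               "increase")
  expect_equal(predict_mechanical_change(list(z = -2), "activate"),
               "decrease")
  expect_error(predict_mechanical_change(list(z = 0), "activate"),
               "no direction")
})

test_that("score_regulators assembles a coherent table", {
  net <- tiny_network()
  obs <- data.frame(gene = c("G1", "G2", "G3", "G4"),
                    direction = c(1L, 1L, -1L, -1L), stringsAsFactors = FALSE)
  sc <- score_regulators(net, obs, n_perm = 200, seed = 2)
  expect_equal(nrow(sc), 2)
  expect_equal(sc$n, c(3L, 2L))
  expect_true(all(sc$n == sc$n_plus + sc$n_minus))
  expect_true(all(sc$p_overlap >= 0 & sc$p_overlap <= 1))
  expect_true(all(sc$p_bias_corrected > 0 & sc$p_bias_corrected <= 1))
})
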