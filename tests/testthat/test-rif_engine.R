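test_that("self-links and perfectly anti-correlated pairs hit the extremes", {
  set.seed(1)
  base <- rnorm(6)
  vals <- rbind(gR = base, gT = base, gU = c(base[1:3], -base[4:6]))
  colnames(vals) <- c(sprintf("S%d", 1:3), sprintf("C%d", 1:3))
  study <- expression_study(vals,
                            setNames(rep(c("S", "C"), c(3, 3)),
                                     colnames(vals)),
                            treated_label = "S", control_label = "C")
  links <- coexpression_links(study, "gR", c("gT", "gU"))
  lt <- links[links$target_id == "gT", ]
  expect_equal(lt$r_S, 1)
  expect_equal(lt$r_C, 1)
  expect_equal(lt$dc, 0)
  lu <- links[links$target_id == "gU", ]
  expect_equal(lu$r_S, 1)
  expect_equal(lu$r_C, -1)
  expect_equal(lu$dc, 2)
  # a regulator that is its own target: r = 1 both sides, DC = 0
  self <- coexpression_links(study, "gR", "gR")
  expect_equal(self$dc, 0)
  expect_equal(self$r_S, 1)
})

test_that("pairwise correlations match the covariance-formula oracle", {
  study <- random_study(n_genes = 80, n_s = 10, n_c = 10, seed = 55)
  regs <- study$gene_ids[1:50]
  tgts <- study$gene_ids[51:80]
  links <- coexpression_links(study, regs, tgts)
  s_cols <- condition_samples(study, "S")
  c_cols <- condition_samples(study, "C")
  idx <- sample(nrow(links), 200)
  for (i in idx) {
    r <- links$regulator_id[i]; t <- links$target_id[i]
    expect_equal(links$r_S[i],
                 cor_oracle(study$values[r, s_cols], study$values[t, s_cols]),
                 tolerance = 1e-12)
    expect_equal(links$r_C[i],
                 cor_oracle(study$values[r, c_cols], study$values[t, c_cols]),
                 tolerance = 1e-12)
    expect_equal(links$dc[i], links$r_S[i] - links$r_C[i], tolerance = 1e-14)
  }
  expect_true(all(abs(links$r_S) <= 1 & abs(links$r_C) <= 1))
  expect_true(all(links$dc >= -2 & links$dc <= 2))
})

test_that("zero-variance genes get r = 0 on the degenerate side, flagged", {
  vals <- rbind(gFlat = c(1, 1, 1, 2, 3, 4),
                gT = c(0.3, -1, 2, 0.5, 1, -0.2))
  colnames(vals) <- c(sprintf("S%d", 1:3), sprintf("C%d", 1:3))
  study <- expression_study(vals,
                            setNames(rep(c("S", "C"), c(3, 3)),
                                     colnames(vals)),
                            treated_label = "S", control_label = "C")
  links <- coexpression_links(study, "gFlat", "gT")
  expect_equal(links$r_S, 0)
  expect_true(links$flagged)
  expect_false(links$r_C == 0)
})

test_that("rif1 and rif2 reproduce hand-evaluated single-target cases", {
  de <- data.frame(gene_id = "gT", x_j = 2, x_jS = 2, x_jC = 1, d_j = 1,
                   stringsAsFactors = FALSE)
  links <- data.frame(regulator_id = "gR", target_id = "gT",
                      r_S = 1, r_C = 1, dc = 1, stringsAsFactors = FALSE)
  expect_equal(rif1(de, links), 2)     # (1/1) * 2 * 1 * 1^2
  expect_equal(rif2(de, links), 3)     # (2*1)^2 - (1*1)^2
  links0 <- transform(links, dc = 0)
  expect_equal(rif1(de, links0), 0)
  # symmetric case: equal abundances and correlations on both sides
  de_sym <- transform(de, x_jS = 1.7, x_jC = 1.7)
  links_sym <- transform(links, r_S = 0.4, r_C = 0.4)
  expect_equal(rif2(de_sym, links_sym), 0)
  expect_error(rif1(de, links[0, ]), "every DE target")
})

test_that("vectorized scores equal the naive loop oracle on random instances", {
  study <- random_study(n_genes = 120, n_s = 8, n_c = 8, seed = 77)
  summ <- summarize_targets(study)
  de <- summ[1:100, ]
  regs <- study$gene_ids[101:120]
  scores <- score_regulators(study, regs, de)
  links <- coexpression_links(study, regs, de$gene_id)
  for (r in regs) {
    lr <- links[links$regulator_id == r, ]
    dc_by <- setNames(as.list(lr$dc), lr$target_id)
    rs_by <- setNames(as.list(lr$r_S), lr$target_id)
    rc_by <- setNames(as.list(lr$r_C), lr$target_id)
    expect_equal(scores$rif1_raw[scores$regulator_id == r],
                 rif1_loop(de, dc_by), tolerance = 1e-10)
    expect_equal(scores$rif2_raw[scores$regulator_id == r],
                 rif2_loop(de, rs_by, rc_by), tolerance = 1e-10)
    # the per-regulator entry points agree with the matrix path too
    expect_equal(scores$rif1_raw[scores$regulator_id == r], rif1(de, lr),
                 tolerance = 1e-12)
    expect_equal(scores$rif2_raw[scores$regulator_id == r], rif2(de, lr),
                 tolerance = 1e-12)
  }
})

test_that("standardized scores have mean 0 and SD 1 across the universe", {
  study <- random_study(n_genes = 60, seed = 31)
  summ <- summarize_targets(study)
  de <- summ[1:30, ]
  scores <- score_regulators(study, study$gene_ids, de)
  expect_equal(mean(scores$rif1_z), 0, tolerance = 1e-10)
  expect_equal(sd(scores$rif1_z), 1, tolerance = 1e-10)
  expect_equal(mean(scores$rif2_z), 0, tolerance = 1e-10)
  expect_equal(sd(scores$rif2_z), 1, tolerance = 1e-10)
  expect_true(all(scores$combined >= 0))
  expect_equal(scores$combined, abs(scores$rif1_z) + abs(scores$rif2_z),
               tolerance = 1e-12)
  expect_setequal(scores$rank, seq_len(nrow(scores)))
  expect_error(score_regulators(study, study$gene_ids[1], de),
               "at least 2 regulators")
})

test_that("condition swap negates raw scores but preserves the ranking", {
  study <- random_study(n_genes = 50, n_s = 7, n_c = 5, seed = 13)
  summ <- summarize_targets(study)
  de <- summ[1:25, ]
  regs <- study$gene_ids
  s1 <- score_regulators(study, regs, de)

  swapped <- swap_roles(study)
  summ2 <- summarize_targets(swapped)
  de2 <- summ2[1:25, ]
  s2 <- score_regulators(swapped, regs, de2)

  i <- match(s1$regulator_id, s2$regulator_id)
  expect_equal(s2$rif1_raw[i], -s1$rif1_raw, tolerance = 1e-10)
  expect_equal(s2$rif2_raw[i], -s1$rif2_raw, tolerance = 1e-10)
  expect_equal(s2$combined[i], s1$combined, tolerance = 1e-10)
  expect_identical(s2$regulator_id, s1$regulator_id)
})

test_that("regulator rescaling leaves RIF untouched (Pearson invariance)", {
  study <- random_study(n_genes = 30, seed = 99)
  summ <- summarize_targets(study)
  de <- summ[1:15, ]
  regs <- study$gene_ids[16:30]
  s1 <- score_regulators(study, regs, de)
  study2 <- study
  study2$values[regs[1], ] <- 3.7 * study2$values[regs[1], ]
  s2 <- score_regulators(study2, regs, de)
  expect_equal(s2$rif1_raw[s2$regulator_id == regs[1]],
               s1$rif1_raw[s1$regulator_id == regs[1]], tolerance = 1e-10)
  expect_equal(s2$rif2_raw[s2$regulator_id == regs[1]],
               s1$rif2_raw[s1$regulator_id == regs[1]], tolerance = 1e-10)
})

test_that("a planted differentially connected regulator outranks null ones", {
  # every competitor is independent noise with no condition-specific
  # coupling; only the planted regulator rewires between S and C
  sim <- simulate_study(sim_config(n_genes = 400, n_de_planted = 60,
                                   block_size = 30, seed = 8))
  study <- sim$study
  summ <- summarize_targets(study)
  de <- select_de_targets(summ, 0.001)
  regs <- c(sim$truth$dc_regulator_ids,
            setdiff(study$gene_ids, sim$truth$dc_regulator_ids)[1:99])
  scores <- score_regulators(study, regs, de)
  planted_rank <- scores$rank[scores$regulator_id ==
                                sim$truth$dc_regulator_ids]
  expect_equal(planted_rank, 1)
})

test_that("ranking is deterministic with lexical tie-break", {
  tab <- rif_rank_table(c("b", "a", "c"), c(1, -1, 2), c(1, 1, 0.5))
  expect_equal(tab$regulator_id, c("c", "a", "b"))
  expect_equal(tab$rank, 1:3)
  # exact tie between a and b (combined 2 each): lexical order decides
  expect_lt(which(tab$regulator_id == "a"), which(tab$regulator_id == "b"))
  half <- rif_rank_table(c("a", "b"), c(2, 1), c(2, 1), combine = "mean_abs")
  expect_equal(half$combined, c(2, 1))
})

test_that("scatter export projects scores and keeps empty input shape", {
  study <- random_study(n_genes = 12, seed = 4)
  summ <- summarize_targets(study)
  scores <- score_regulators(study, study$gene_ids, summ[1:6, ])
  sc <- export_rif_scatter(scores)
  expect_equal(nrow(sc), nrow(scores))
  expect_identical(sc$label, scores$regulator_id)
  empty <- export_rif_scatter(scores[0, ])
  expect_equal(nrow(empty), 0)
  expect_identical(colnames(empty), c("rif1_z", "rif2_z", "label"))
})
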