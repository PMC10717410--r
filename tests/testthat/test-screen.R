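test_that("screen applies strict thresholds and the epi-zero rule", {
  tab <- data.frame(
    gene_id = c("boundary", "clear", "ratio_fail", "epi_zero", "low"),
    rpkm_cvp = c(10.0, 50, 40, 25, 2),
    rpkm_epi = c(1, 5, 20, 0, 0.1))
  res <- screen_candidates(tab)
  # cvp = 10.0 fails the strict >, ratio 2 fails, epi 0 passes as +Inf
  expect_equal(res$passing, c("clear", "epi_zero"))
  expect_equal(res$table$ratio[res$table$gene_id == "epi_zero"], Inf)
  # order preserved
  expect_equal(res$table$gene_id, tab$gene_id)
})

test_that("screen validates its input", {
  expect_error(screen_candidates(
    data.frame(gene_id = c("a", "a"), rpkm_cvp = c(20, 30),
               rpkm_epi = c(1, 1))), "duplicate")
  expect_error(screen_candidates(
    data.frame(gene_id = "a", rpkm_cvp = -1, rpkm_epi = 1)), "finite")
  expect_error(screen_candidates(data.frame(x = 1)), "columns")
})

test_that("screen recovers planted gene sets exactly", {
  for (seed in c(1, 7, 99)) {
    tab <- gen_expression_table(n_genes = 500, n_planted_pass = 17,
                                seed = seed)
    res <- screen_candidates(tab)
    expect_equal(sort(res$passing), attr(tab, "planted"))
    # independent brute-force row check
    brute <- tab$gene_id[apply(tab, 1, function(r) {
      cvp <- as.numeric(r[["rpkm_cvp"]]); epi <- as.numeric(r[["rpkm_epi"]])
      cvp > 10 && (epi == 0 || cvp / epi > 3)
    })]
    expect_equal(res$passing, as.character(brute))
  }
})

test_that("raising either threshold never adds a gene", {
  tab <- gen_expression_table(n_genes = 400, n_planted_pass = 40, seed = 3)
  base <- screen_candidates(tab)$passing
  for (thr in list(c(20, 3), c(10, 6), c(35, 10))) {
    tighter <- screen_candidates(tab, min_cvp = thr[1],
                                 min_ratio = thr[2])$passing
    expect_true(all(tighter %in% base))
  }
})

test_that("screening distributes over disjoint tables", {
  tab <- gen_expression_table(n_genes = 200, n_planted_pass = 12, seed = 5)
  a <- tab[1:80, ]; b <- tab[81:200, ]
  expect_equal(sort(c(screen_candidates(a)$passing,
                      screen_candidates(b)$passing)),
               sort(screen_candidates(tab)$passing))
})

test_that("family flagging intersects with the passing set", {
  tab <- gen_expression_table(n_genes = 100, n_planted_pass = 0, seed = 2)
  # plant a Tmc-like family: 8 members, exactly 3 passing
  fam <- data.frame(
    gene_id = sprintf("Tmc%d", 1:8),
    rpkm_cvp = c(1, 2, 3, 60, 45, 0.5, 30, 8),
    rpkm_epi = c(1, 1, 1, 2, 3, 1, 0, 1))
  res <- screen_candidates(rbind(tab, fam))
  expect_equal(flag_family(res, "Tmc", prefix = TRUE),
               c("Tmc4", "Tmc5", "Tmc7"))
  expect_equal(flag_family(res, sprintf("Tmc%d", 1:8)),
               c("Tmc4", "Tmc5", "Tmc7"))
  # disjoint family: empty; whole-gene-list family: identity
  expect_length(flag_family(res, c("Ano1", "Ano2")), 0)
  expect_equal(flag_family(res, res$table$gene_id), res$passing)
})
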