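test_that("generated networks honour the cell's structural contract", {
  set.seed(50)
  cat3 <- build_catalogue(3, 0.25)
  net <- generate_rbn(20, cat3, 1.5)
  expect_equal(network_size(net), 20L)
  expect_equal(network_in_degrees(net), rep(3L, 20))
  expect_equal(network_biases(net), rep(0.25, 20))
  kes <- vapply(network_rules(net), effective_connectivity, numeric(1))
  expect_true(all(ke_bin(kes) == 1.5))
  expect_equal(attr(net, "mean_ke"), mean(kes))
  # inputs are distinct per node
  for (ins in net$inputs) expect_equal(anyDuplicated(ins), 0L)
})

test_that("the parity bin at (k=2, p=0.5) yields pure parity networks", {
  set.seed(51)
  cat22 <- build_catalogue(2, 0.5)
  net <- generate_rbn(10, cat22, 2.0)
  expect_equal(network_mean_ke(net), 2)
  for (r in network_rules(net)) {
    expect_true(identical(r$outputs, c(0L, 1L, 1L, 0L)) ||
                identical(r$outputs, c(1L, 0L, 0L, 1L)))
  }
  expect_error(generate_rbn(10, cat22, 1.5), class = "canalcrit_empty_bin")
})

test_that("ensemble sweeps are homogeneous, annotated and reproducible", {
  spec <- ensemble_spec(N = 12L, k = 2L, p_step = 0.25, replicates = 2L,
                        seed = 123L)
  cats <- build_catalogues(spec)
  ens1 <- generate_ensemble(spec, cats)
  ens2 <- generate_ensemble(spec, cats)
  # p grid {0.25, 0.5} x bins {1, 1.5, 2}: cell (p=0.25, bin 1.0/2.0) and
  # (p=0.5, bin 1.5) are unviable at k = 2
  expect_lte(nrow(ens1$manifest), 12L)
  expect_gt(nrow(ens1$manifest), 0L)
  expect_equal(nrow(ens1$manifest) + 2L * nrow(ens1$skipped), 12L)
  expect_identical(ens1$manifest, ens2$manifest)
  for (i in seq_along(ens1$networks)) {
    a <- ens1$networks[[i]]; b <- ens2$networks[[i]]
    expect_identical(a$inputs, b$inputs)
    expect_identical(lapply(a$rules, `[[`, "outputs"),
                     lapply(b$rules, `[[`, "outputs"))
    row <- ens1$manifest[i, ]
    expect_equal(network_in_degrees(a), rep(as.integer(row$k), 12))
    expect_equal(network_biases(a), rep(row$p, 12))
    expect_true(all(ke_bin(vapply(network_rules(a), effective_connectivity,
                                  numeric(1))) == row$bin))
  }
})

test_that("cells can be regenerated independently via their recorded seed", {
  spec <- ensemble_spec(N = 10L, k = 2L, p_step = 0.25, replicates = 3L,
                        seed = 7L)
  cats <- build_catalogues(spec)
  ens <- generate_ensemble(spec, cats)
  row <- ens$manifest[ens$manifest$replicate == 1L, ][2, ]
  idx <- which(ens$manifest$k == row$k & ens$manifest$p == row$p &
                 ens$manifest$bin == row$bin)
  set.seed(row$cell_seed)
  cat_kp <- cats[[sprintf("k=%d,p=%.10g", row$k, row$p)]]
  redo <- lapply(seq_len(3), function(r) generate_rbn(10, cat_kp, row$bin))
  for (j in seq_along(idx)) {
    expect_identical(redo[[j]]$inputs, ens$networks[[idx[j]]]$inputs)
  }
})

test_that("network_fn streams per-network results into the manifest", {
  spec <- ensemble_spec(N = 10L, k = 2L, p_step = 0.5, replicates = 2L,
                        seed = 3L)
  cats <- build_catalogues(spec)
  ens <- generate_ensemble(spec, cats,
                           network_fn = function(net, row)
                             list(mk = network_mean_ke(net)))
  expect_null(ens$networks)
  expect_true("mk" %in% names(ens$manifest))
  expect_equal(ens$manifest$mk, ens$manifest$mean_ke)
})

test_that("the bias grid is clipped to attainable multiples of p_step", {
  spec <- ensemble_spec(N = 5L, k = c(2L, 4L), p_step = c(0.25, 1 / 16),
                        seed = 1L)
  expect_equal(canalcrit:::p_grid(spec, 1), c(0.25, 0.5))
  expect_equal(canalcrit:::p_grid(spec, 2), seq(1 / 16, 0.5, by = 1 / 16))
  expect_error(ensemble_spec(k = 2L, p_step = 0.3), "multiple")
})
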