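# small reusable fixture: a paired simulation with planted duplicates,
# built once per test file
tiny_sim <- simulate_paired_datasets(n_pixels = 100, n_genes = 24,
                                     n_cells = 120, n_types = 3,
                                     n_modules = 4, n_duplicate_pairs = 2,
                                     seed = 42)

test_that("cell-type centers equal per-type means", {
  # one cell per type: the center is that cell's profile
  counts <- matrix(c(1, 5, 2, 8, 0, 3), 2, 3,
                   dimnames = list(NULL, c("g1", "g2", "g3")))
  sc1 <- sc_dataset(counts, c("A", "B"))
  ce1 <- cell_type_centers(sc1, normalization = "raw")
  expect_equal(unname(ce1["A", ]), unname(counts[1, ]))
  expect_equal(unname(ce1["B", ]), unname(counts[2, ]))

  # two cells of one type with counts 2 and 4: raw center is 3
  sc2 <- sc_dataset(matrix(c(2, 4), 2, 1, dimnames = list(NULL, "g1")),
                    c("A", "A"))
  expect_equal(unname(cell_type_centers(sc2, normalization = "raw")[1, 1]), 3)
})

test_that("centers agree with a brute-force group-by mean oracle", {
  set.seed(10)
  counts <- matrix(rpois(50 * 30, 4), 50, 30,
                   dimnames = list(NULL, sprintf("g%02d", 1:30)))
  labels <- sample(paste0("t", 1:5), 50, replace = TRUE)
  sc <- sc_dataset(counts, labels)
  for (norm in c("raw", "lognorm")) {
    ce <- cell_type_centers(sc, normalization = norm)
    expr <- if (norm == "raw") counts else
      log1p(counts / rowSums(counts) * 1e4)
    for (t in sort(unique(labels)))
      expect_equal(unname(ce[t, ]),
                   unname(apply(expr[labels == t, , drop = FALSE], 2, mean)))
  }
})

test_that("pixels are assigned the best-correlated center", {
  # pixel profile exactly proportional to one center: correlation 1
  counts <- rbind(c(10, 1, 1), c(1, 10, 1))
  colnames(counts) <- c("g1", "g2", "g3")
  sc <- sc_dataset(counts, c("A", "B"))
  centers <- cell_type_centers(sc, normalization = "raw")
  px <- rbind(c(20, 2, 2), c(2, 20, 2), c(30, 3, 3))
  colnames(px) <- colnames(counts)
  sp <- spatial_dataset(px, cbind(1:3, 1:3))
  asg <- assign_pixels(sp, centers, c("g1", "g2", "g3"))
  expect_equal(asg$assignment$cell_type, c("A", "B", "A"))
  # depth normalization makes the match exact up to log1p curvature
  expect_gt(min(asg$assignment$correlation), 0.99)
  # covariate table: x[i, g] is the assigned center's value of g
  expect_equal(unname(asg$x[1, ]), unname(centers["A", ]))

  # single anti-correlated candidate is still the forced argmax
  sc1 <- sc_dataset(matrix(c(10, 5, 1), 1, 3,
                           dimnames = list(NULL, c("g1", "g2", "g3"))), "A")
  ce1 <- cell_type_centers(sc1, normalization = "raw")
  m1 <- rbind(c(1, 5, 10), c(1, 5, 10))
  colnames(m1) <- c("g1", "g2", "g3")
  sp1 <- spatial_dataset(m1, cbind(1:2, 1:2))
  asg1 <- assign_pixels(sp1, ce1, c("g1", "g2", "g3"))
  expect_equal(asg1$assignment$cell_type, c("A", "A"))
  expect_lt(asg1$assignment$correlation[1], 0)
})

test_that("assignment matches a brute-force per-pixel correlation loop", {
  centers <- cell_type_centers(tiny_sim$paired$sc)
  asg <- assign_pixels(tiny_sim$paired$spatial, centers,
                       tiny_sim$paired$shared_genes)
  sp <- tiny_sim$paired$spatial
  px <- log1p(sp$counts / sp$size_factors * 1e4)
  px <- px[, tiny_sim$paired$shared_genes]
  ce <- centers[, tiny_sim$paired$shared_genes]
  for (i in seq_len(nrow(px))) {
    cors <- sapply(rownames(ce), function(t) cor(px[i, ], ce[t, ]))
    expect_equal(asg$assignment$cell_type[i], names(which.max(cors)))
    expect_equal(asg$assignment$correlation[i], unname(max(cors)))
  }
})

test_that("assignment is invariant to per-pixel positive rescaling", {
  centers <- cell_type_centers(tiny_sim$paired$sc)
  sp <- tiny_sim$paired$spatial
  asg0 <- assign_pixels(sp, centers, tiny_sim$paired$shared_genes)
  scaled <- sp$counts
  scaled[3, ] <- scaled[3, ] * 7    # integer rescale of one pixel
  sp2 <- spatial_dataset(scaled, sp$coords)
  asg1 <- assign_pixels(sp2, centers, tiny_sim$paired$shared_genes)
  expect_equal(asg1$assignment$cell_type, asg0$assignment$cell_type)
})

test_that("constant pixel profiles fall back to the most common type", {
  counts <- rbind(c(10, 1, 2), c(9, 2, 1), c(3, 3, 3))
  colnames(counts) <- c("g1", "g2", "g3")
  sc <- sc_dataset(rbind(c(10, 1, 2), c(1, 10, 2)), c("A", "B"))
  colnames(sc$counts) <- sc$gene_names <- c("g1", "g2", "g3")
  sp <- spatial_dataset(counts, cbind(1:3, 1:3))
  expect_warning(asg <- assign_pixels(sp, cell_type_centers(sc, "raw"),
                                      c("g1", "g2", "g3")),
                 "most common")
  expect_equal(asg$assignment$cell_type[3], "A")
  expect_true(is.na(asg$assignment$correlation[3]))
})

test_that("the reference set keeps exactly the genes passing the cut", {
  centers <- cell_type_centers(tiny_sim$paired$sc)
  asg <- assign_pixels(tiny_sim$paired$spatial, centers,
                       tiny_sim$paired$shared_genes)
  kern <- list(kind = "car", alpha_s = 0.5)
  refs_all <- build_reference_set(tiny_sim$paired, asg, kern, p_cut = 1)
  ok <- !is.na(refs_all$table$p_value)
  expect_setequal(names(refs_all$fits), refs_all$table$gene[ok])

  refs <- build_reference_set(tiny_sim$paired, asg, kern, p_cut = 0.05)
  expect_true(all(refs$table$p_value[refs$table$kept] < 0.05))
  # strong-signal genes (beta = 1, n = 100) are mostly detected
  sig <- tiny_sim$truth$genes[tiny_sim$truth$is_signal]
  expect_gt(mean(sig %in% names(refs$fits)), 0.6)
  expect_error(build_reference_set(tiny_sim$paired, asg, kern, p_cut = 1e-300),
               "looser")
})

test_that("reference selection finds planted correlates and breaks ties lexicographically", {
  centers <- cell_type_centers(tiny_sim$paired$sc)
  asg <- assign_pixels(tiny_sim$paired$spatial, centers,
                       tiny_sim$paired$shared_genes)
  kern <- list(kind = "car", alpha_s = 0.5)
  refs <- build_reference_set(tiny_sim$paired, asg, kern, p_cut = 1)

  # genes 1/2 and 3/4 are exact single-cell duplicates
  sel <- select_reference_gene("gene001", refs, tiny_sim$paired$sc)
  expect_equal(sel$gene, "gene001")      # itself, correlation exactly 1
  expect_equal(sel$correlation, 1)

  refs_no_self <- refs
  refs_no_self$fits <- refs$fits[setdiff(names(refs$fits), "gene001")]
  sel2 <- select_reference_gene("gene001", refs_no_self, tiny_sim$paired$sc)
  expect_equal(sel2$gene, "gene002")     # the planted duplicate
  expect_equal(sel2$correlation, 1)

  # reordering the non-selected references never changes the answer
  refs_shuffled <- refs_no_self
  set.seed(1)
  refs_shuffled$fits <- refs_shuffled$fits[sample(names(refs_shuffled$fits))]
  sel3 <- select_reference_gene("gene001", refs_shuffled, tiny_sim$paired$sc)
  expect_equal(sel3$gene, sel2$gene)

  # duplicated columns tie at the same correlation: lexicographic winner
  dup_target <- "gene003"   # duplicates gene003/gene004
  refs_pair <- refs
  refs_pair$fits <- refs$fits[intersect(names(refs$fits),
                                        c("gene003", "gene004"))]
  sel4 <- select_reference_gene(dup_target, refs_pair, tiny_sim$paired$sc)
  expect_equal(sel4$gene, "gene003")

  expect_error(select_reference_gene("absent", refs, tiny_sim$paired$sc),
               "missing")
})

test_that("constant single-cell targets are rejected", {
  counts <- cbind(g1 = c(5L, 5L, 5L), g2 = c(1L, 4L, 9L), g3 = c(2L, 3L, 4L))
  sc <- sc_dataset(counts, c("A", "A", "B"))
  # build a reference set on the tiny sim but swap in this sc for selection
  centers <- cell_type_centers(tiny_sim$paired$sc)
  asg <- assign_pixels(tiny_sim$paired$spatial, centers,
                       tiny_sim$paired$shared_genes)
  refs <- build_reference_set(tiny_sim$paired, asg,
                              list(kind = "car", alpha_s = 0.5), p_cut = 1)
  sc_const <- tiny_sim$paired$sc
  sc_const$counts[, "gene005"] <- 3L
  expect_error(select_reference_gene("gene005", refs, sc_const,
                                     transform = "raw"),
               "constant")
})

test_that("prediction applies the fitted parameters to the target covariate", {
  centers <- cell_type_centers(tiny_sim$paired$sc)
  asg <- assign_pixels(tiny_sim$paired$spatial, centers,
                       tiny_sim$paired$shared_genes)
  refs <- build_reference_set(tiny_sim$paired, asg,
                              list(kind = "car", alpha_s = 0.5), p_cut = 1)
  pred <- predict_gene("gene001", refs, asg, tiny_sim$paired$sc)
  fit <- refs$fits[[pred$reference_gene]]
  expect_equal(pred$table$lambda_hat,
               exp(unname(coef(fit)["alpha"]) +
                     asg$x[, "gene001"] * unname(coef(fit)["beta"]) +
                     fit$g + fit$e),
               ignore_attr = TRUE)
  expect_equal(pred$table$predicted_count,
               unname(fit$offset * pred$table$lambda_hat))

  # intercept-only collapse: with beta, g, e all zero the rate is constant
  fit0 <- fit
  fit0$coefficients["beta"] <- 0
  fit0$g[] <- 0; fit0$e[] <- 0
  lam <- predict(fit0, newx = asg$x[, "gene001"], type = "rate")
  expect_equal(unname(lam), rep(exp(unname(coef(fit0)["alpha"])),
                                length(lam)))

  # sampling is reproducible under a fixed seed
  s1 <- predict_gene("gene001", refs, asg, tiny_sim$paired$sc,
                     mode = "sample", seed = 9)
  s2 <- predict_gene("gene001", refs, asg, tiny_sim$paired$sc,
                     mode = "sample", seed = 9)
  expect_identical(s1$table$sampled_count, s2$table$sampled_count)
  expect_error(predict_gene("absent", refs, asg, tiny_sim$paired$sc),
               "missing")
})

test_that("self-prediction of a strongly fit gene reproduces its own pattern", {
  sim <- simulate_paired_datasets(n_pixels = 300, n_genes = 20, n_cells = 200,
                                  n_types = 4, n_modules = 4,
                                  null_fraction = 0, seed = 5)
  centers <- cell_type_centers(sim$paired$sc)
  asg <- assign_pixels(sim$paired$spatial, centers, sim$paired$shared_genes)
  refs <- build_reference_set(sim$paired, asg,
                              list(kind = "car", alpha_s = 0.5), p_cut = 1)
  g <- names(refs$fits)[1L]
  pred <- predict_gene(g, refs, asg, sim$paired$sc, reference_gene = g)
  r <- pearson_cor(sim$paired$spatial$counts[, g], pred$table$predicted_count)
  expect_gt(r, 0.9)
})

test_that("held-out genes sharing their reference's random effects are recovered", {
  # one reference gene and one target generated from the same (g, e)
  # realization with beta = 1; the target is predicted from the
  # reference's fit and must beat a permuted-reference baseline
  rs <- numeric(); rs_perm <- numeric()
  for (s in 1:5) {
    ref_sim <- simulate_glsm_counts(n = 300, alpha = -1, beta = 1, sigma2 = 1,
                                    h2 = 0.6, seed = s)
    set.seed(1000 + s)
    x_tgt <- rnorm(300)
    lam_tgt <- exp(-1 + x_tgt * 1 + ref_sim$truth$g + ref_sim$truth$e)
    y_tgt <- rpois(300, ref_sim$offset * lam_tgt)
    fit <- suppressWarnings(glsm(ref_sim$y, ref_sim$x, ref_sim$kernel,
                                 offset = ref_sim$offset))
    pred <- predict(fit, newx = x_tgt, type = "count")
    rs[s] <- cor(y_tgt, pred)
    perm <- sample(length(pred))
    rs_perm[s] <- cor(y_tgt, pred[perm])
  }
  expect_gte(mean(rs), 0.5)
  expect_gt(mean(rs), mean(rs_perm))
})

test_that("simulated pixel types are recovered when centers are well separated", {
  sim <- simulate_paired_datasets(n_pixels = 200, n_genes = 100,
                                  n_cells = 500, n_types = 5, n_modules = 25,
                                  center_sd = 2, profile_noise_sd = 0.1,
                                  null_fraction = 0, beta = 2, sigma2 = 0.25,
                                  seed = 7)
  centers <- cell_type_centers(sim$paired$sc)
  asg <- assign_pixels(sim$paired$spatial, centers, sim$paired$shared_genes)
  expect_gte(mean(asg$assignment$cell_type == sim$truth$pixel_type), 0.9)
})
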