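test_that("pearson distance matches hand-computed anchors", {
  x <- c(1.2, 2.4, 3.1, 0.5)
  expect_equal(pearson_distance(x, x), 0)
  expect_equal(pearson_distance(x, -x), 2)
  expect_equal(pearson_distance(c(1, 2, 3), c(1, 3, 2)), 0.5) # r = 0.5 by hand
  expect_error(pearson_distance(1:3, 1:4), "length")
  d <- pearson_distance(c(1, 1, 1), c(1, 2, 3))
  expect_equal(as.numeric(d), 1)
  expect_true(attr(d, "zero_variance"))
})

test_that("call strength follows the silhouette formula", {
  expect_equal(call_strength(c(a = 0, b = 0.6), "a"), 1)
  expect_equal(call_strength(c(a = 0.3, b = 0.3), "a"), 0)
  expect_equal(call_strength(c(a = 0.2, b = 0.6, c = 0.9), "a"), 0.4 / 0.6)
  deg <- call_strength(c(a = 0, b = 0), "a")
  expect_equal(as.numeric(deg), 0)
  expect_true(attr(deg, "degenerate"))
  expect_error(call_strength(c(a = 0.5, b = 0.2), "a"), "minimum")
})

test_that("clanc statistics equal a brute-force evaluation of the formula", {
  toy <- toy_two_class()
  stats <- clanc_statistics(toy$expr, toy$labels, sd_floor = 0.05)
  oracle <- oracle_clanc(as_expression_matrix(toy$expr), toy$labels,
                         c("A", "B"), sd_floor = 0.05)
  merged <- merge(as.data.frame(stats), oracle, by = c("gene", "class"))
  expect_equal(merged$statistic.x, merged$statistic.y, tolerance = 1e-12)

  # signs: g_up positive in A, negative in B; constant gene exactly 0
  s <- function(g, cl) stats$statistic[stats$gene == g & stats$class == cl]
  expect_gt(s("g_up", "A"), 0)
  expect_lt(s("g_up", "B"), 0)
  expect_equal(s("g_flat", "A"), 0)
  expect_equal(s("g_flat", "B"), 0)

  expect_error(clanc_statistics(toy$expr, c("A", rep("B", 5))), ">= 2 samples")
})

test_that("balanced selection takes per-class extremes and resolves contention round-robin", {
  toy <- toy_two_class()
  stats <- clanc_statistics(toy$expr, toy$labels)
  sel <- select_balanced_genes(stats, total_genes = 4)
  expect_equal(nrow(sel), 4)
  # highs are claimed first (A then B), so each class gets its top gene;
  # for the lows the extremes are already claimed by the other class's high
  # pick, leaving the mild mirror genes
  expect_equal(sel$gene[sel$class == "A" & sel$direction == "high"], "g_up")
  expect_equal(sel$gene[sel$class == "B" & sel$direction == "high"], "g_dn")
  expect_equal(sel$gene[sel$class == "A" & sel$direction == "low"], "g_dn2")
  expect_equal(sel$gene[sel$class == "B" & sel$direction == "low"], "g_up2")
  expect_equal(anyDuplicated(sel$gene), 0)
  expect_error(select_balanced_genes(stats, 6), "divisible")
})

test_that("contended genes go to the earlier class; the later class takes its next rank", {
  # one shared top gene: elevated in A and depressed in B symmetrically
  values <- rbind(
    shared = c(9, 9.5, 9.2, 1, 1.5, 1.2),
    a_next = c(6, 6.5, 6.2, 3, 3.5, 3.2),
    b_top = c(1, 1.2, 1.1, 7, 7.5, 7.2),
    filler1 = c(4, 4.6, 4.2, 4.1, 4.4, 4.3),
    filler2 = c(5, 5.2, 5.1, 5.0, 5.3, 4.9)
  )
  colnames(values) <- paste0("s", 1:6)
  labels <- rep(c("A", "B"), each = 3)
  stats <- clanc_statistics(expression_tibble(values, "log2"), labels)
  # "shared" is rank-1 high for A and rank-1 low for B; A claims first
  sel <- select_balanced_genes(stats, 4)
  expect_equal(sel$gene[sel$class == "A" & sel$direction == "high"], "shared")
  expect_false("shared" %in% sel$gene[sel$class == "B"])
  expect_equal(anyDuplicated(sel$gene), 0)
  expect_equal(sum(sel$class == "B"), 2)
})

test_that("centroid coefficients are hand-computed medians of median-centred values", {
  values <- rbind(
    gA_hi = c(5, 7, 1, 2), gA_lo = c(1, 2, 5, 7),
    gB_hi = c(0, 1, 8, 9), gB_lo = c(8, 9, 0, 1)
  )
  colnames(values) <- paste0("s", 1:4)
  labels <- c("A", "A", "B", "B")
  sel <- tibble::tibble(gene = rownames(values),
                        class = c("A", "A", "B", "B"),
                        direction = c("high", "low", "high", "low"))
  model <- compute_centroids(expression_tibble(values, "log2"), labels, sel,
                             q = 0)
  expect_equal(model$gene_overall_median, c(3.5, 3.5, 4.5, 4.5))
  expect_equal(unname(model$coefficients[, "A"]), c(2.5, -2, -4, 4))
  expect_equal(unname(model$coefficients[, "B"]), c(-2, 2.5, 4, -4))
})

test_that("call-strength exclusion removes exactly floor(q * n_k) per class", {
  cfg <- sim_config(n_samples = 100, n_marker_genes_per_subtype = 4,
                    n_noise_genes = 10,
                    subtype_proportions = c(basal = 0.25, mesenchymal = 0.25,
                                            classical = 0.25, atypical = 0.25),
                    seed = 44)
  sim <- simulate_expression(cfg)
  strengths <- tibble::tibble(sample_id = sim$labels$sample_id,
                              call_strength = seq(0, 1, length.out = 100))
  stats <- clanc_statistics(sim$expression, sim$labels)
  sel <- select_balanced_genes(stats, 16)
  model <- compute_centroids(sim$expression, sim$labels, sel,
                             strengths = strengths, q = 0.2)
  n_k <- table(sim$labels$subtype)
  expect_equal(length(attr(model, "excluded_samples")),
               sum(floor(0.2 * n_k)))
  # per class, exactly floor(0.2 * n_k) lowest-strength samples removed
  excl <- attr(model, "excluded_samples")
  for (st in hnscc_subtypes) {
    ids <- sim$labels$sample_id[sim$labels$subtype == st]
    st_str <- strengths$call_strength[match(ids, strengths$sample_id)]
    expected <- ids[order(st_str)][seq_len(floor(0.2 * length(ids)))]
    expect_setequal(intersect(excl, ids), expected)
  }
  # q = 0 keeps everyone
  m0 <- compute_centroids(sim$expression, sim$labels, sel, q = 0)
  expect_length(attr(m0, "excluded_samples"), 0)
  # stored centring constants are the medians over retained samples
  retained <- attr(model, "retained_samples")
  values <- as_expression_matrix(sim$expression)
  expect_equal(model$gene_overall_median,
               unname(apply(values[model$genes, retained], 1, median)))
})

test_that("classification recovers a centroid exactly and respects the tie rule", {
  toy <- toy_two_class()
  model <- train_centroid_model(toy$expr, toy$labels, total_genes = 4)
  # sample equal to a centroid column
  probe <- model$coefficients[, "A"]
  pm <- matrix(probe, ncol = 1, dimnames = list(model$genes, "probe"))
  call <- classify_samples(expression_tibble(pm, "log2"), model)
  expect_equal(call$subtype, "A")
  expect_equal(call$dist_A, 0, tolerance = 1e-12)
  expect_equal(call$call_strength, 1, tolerance = 1e-9)

  # proportional centroids make every sample an exact tie -> first label wins
  coefs <- cbind(first = c(1, -2, 3, -1), second = 2 * c(1, -2, 3, -1))
  rownames(coefs) <- paste0("g", 1:4)
  tie_model <- new_centroid_model(
    subtype_names = c("first", "second"), genes = rownames(coefs),
    coefficients = coefs,
    gene_assignment = c("first", "first", "second", "second"),
    gene_direction = c("high", "low", "high", "low"),
    gene_overall_median = rep(0, 4)
  )
  pm2 <- matrix(rnorm(4), ncol = 1, dimnames = list(rownames(coefs), "x"))
  tie_call <- classify_samples(expression_tibble(pm2, "log2"), tie_model)
  expect_equal(tie_call$subtype, "first")
  expect_true(tie_call$tie)
})

test_that("distances and call strengths stay in range on simulated cohorts", {
  sim <- simulate_expression(small_sim(n = 50, seed = 77))
  model <- train_centroid_model(sim$expression, sim$labels, total_genes = 16)
  calls <- classify_samples(sim$expression, model)
  d <- as.matrix(calls[, paste0("dist_", model$subtype_names)])
  expect_true(all(d >= 0 & d <= 2))
  expect_true(all(calls$call_strength >= -1 & calls$call_strength <= 1))
  expect_true(all(vapply(seq_len(nrow(calls)), function(i) {
    calls$subtype[i] == model$subtype_names[which.min(d[i, ])]
  }, logical(1))))
})

test_that("classification is invariant under per-sample affine maps", {
  sim <- simulate_expression(small_sim(n = 40, seed = 55))
  model <- train_centroid_model(sim$expression, sim$labels, total_genes = 16)
  base <- classify_samples(sim$expression, model)
  values <- as_expression_matrix(sim$expression)
  set.seed(1)
  a <- runif(ncol(values), 0.2, 5)
  b <- rnorm(ncol(values), 0, 10)
  warped <- sweep(sweep(values, 2, a, "*"), 2, b, "+")
  warped_calls <- classify_samples(expression_tibble(warped, "log2"), model)
  expect_equal(warped_calls$subtype, base$subtype)
  expect_equal(warped_calls$call_strength, base$call_strength, tolerance = 1e-9)
})

test_that("cross-validated agreement separates signal from permuted labels", {
  sim <- simulate_expression(small_sim(n = 80, effect = 4, seed = 66))
  gold <- train_centroid_model(sim$expression, sim$labels, total_genes = 16)
  gold_calls <- classify_samples(sim$expression, gold)
  cfg <- training_config(total_genes = 16, seed = 66)
  cv <- cross_validate_size(sim$expression, gold_calls, c(8, 16), cfg)
  expect_equal(nrow(cv), 2)
  expect_true(all(cv$mean_agreement >= 0.95))

  perm <- gold_calls
  set.seed(12)
  perm$subtype <- sample(perm$subtype)
  cv_null <- cross_validate_size(sim$expression, perm, 16, cfg)
  expect_lt(cv_null$mean_agreement, 0.7)
})

test_that("the reduced-classifier builder honours pool and size settings", {
  sim <- simulate_expression(small_sim(n = 120, seed = 10, markers = 10,
                                       noise = 80))
  gold <- train_centroid_model(sim$expression, sim$labels, total_genes = 40)
  fit <- build_reduced_classifier(
    sim$expression, gold, training_config(total_genes = 24, seed = 10))
  expect_s3_class(fit$model, "centroid_model")
  expect_length(fit$model$genes, 24)
  # reduced calls agree with gold calls on well-separated data
  reduced_calls <- classify_samples(sim$expression, fit$model)
  expect_gte(mean(reduced_calls$subtype == fit$gold_calls$subtype), 0.9)

  # no extra candidates -> pool is exactly the gold gene set
  fit0 <- build_reduced_classifier(
    sim$expression, gold,
    training_config(total_genes = 24, candidate_extra_genes = 0, seed = 10))
  expect_setequal(fit0$candidate_pool, gold$genes)
})

test_that("centroid models round-trip through TSV serialisation", {
  sim <- simulate_expression(small_sim(n = 40, seed = 23))
  model <- train_centroid_model(sim$expression, sim$labels, total_genes = 16)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_centroid_model(model, path)
  back <- read_centroid_model(path)
  expect_equal(back$subtype_names, model$subtype_names)
  expect_equal(back$coefficients, model$coefficients, tolerance = 1e-12)
  expect_equal(back$gene_direction, model$gene_direction)
  # identical classifications after reload
  a <- classify_samples(sim$expression, model)
  b <- classify_samples(sim$expression, back)
  expect_equal(a$subtype, b$subtype)
})

test_that("the binary node predictor learns signal and stays at chance under none", {
  # node status driven by class-specific marker blocks
  set.seed(31)
  n <- 80
  node <- rep(c("N0", "N+"), each = n / 2)
  values <- matrix(rnorm(40 * n), 40, n,
                   dimnames = list(sprintf("g%02d", 1:40), sprintf("s%03d", 1:n)))
  values[1:5, node == "N+"] <- values[1:5, node == "N+"] + 4
  values[6:10, node == "N+"] <- values[6:10, node == "N+"] - 4
  values[11:15, node == "N0"] <- values[11:15, node == "N0"] + 4
  values[16:20, node == "N0"] <- values[16:20, node == "N0"] - 4
  expr <- expression_tibble(values, "log2")
  fit <- train_binary_node_predictor(expr, node,
                                     training_config(total_genes = 8, seed = 31))
  expect_equal(fit$train_accuracy, 1)
  expect_gt(fit$cv_accuracy, 0.9)

  # label-independent expression -> CV accuracy near the majority frequency
  null_fit <- train_binary_node_predictor(
    expr, sample(node), training_config(total_genes = 8, seed = 32))
  expect_lt(null_fit$cv_accuracy, 0.75)
  expect_error(train_binary_node_predictor(expr, rep("N0", n)), "both classes")
})
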