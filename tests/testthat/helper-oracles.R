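# Independent oracles and tiny fixture builders. These deliberately avoid
# the package's own code paths (and the wrapped stats/survival routines)
# so that tests compare two independent computations.

# Two-sided Fisher p by full hypergeometric enumeration over all tables
# with the observed margins.
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(xs, function(x) {
    exp(lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1))
  }, numeric(1))
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Direct evaluation of the per-class t-statistic formula, gene by gene.
oracle_clanc <- function(values, labels, classes, sd_floor) {
  n <- ncol(values)
  k <- length(classes)
  out <- expand.grid(gene = rownames(values), class = classes,
                     stringsAsFactors = FALSE)
  out$statistic <- NA_real_
  for (i in seq_len(nrow(out))) {
    g <- out$gene[i]
    cl <- out$class[i]
    x <- values[g, ]
    ss <- 0
    for (c2 in classes) {
      xi <- x[labels == c2]
      ss <- ss + sum((xi - mean(xi))^2)
    }
    s_g <- max(sqrt(ss / (n - k)), sd_floor)
    n_k <- sum(labels == cl)
    m_k <- sqrt(1 / n_k - 1 / n)
    out$statistic[i] <- (mean(x[labels == cl]) - mean(x)) / (m_k * s_g)
  }
  out
}

# Hand product-limit estimator (events before censorings at ties).
oracle_km <- function(times, events) {
  ts <- sort(unique(times[events == 1]))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    at_risk <- sum(times >= ts[i])
    d <- sum(times == ts[i] & events == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  tibble::tibble(time = ts, survival = surv)
}

# Two-group log-rank statistic from the O-E / variance formula.
oracle_logrank <- function(time1, event1, time2, event2) {
  times <- c(time1, time2)
  events <- c(event1, event2)
  grp <- rep(1:2, c(length(time1), length(time2)))
  ts <- sort(unique(times[events == 1]))
  o1 <- e1 <- v <- 0
  for (t in ts) {
    n_t <- sum(times >= t)
    n1 <- sum(times >= t & grp == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & grp == 1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n_t
    if (n_t > 1) v <- v + d * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d) / (n_t - 1)
  }
  (o1 - e1)^2 / v
}

# A tiny two-class expression fixture with a known structure: g_up / g_up2
# are strongly / mildly elevated in class A, g_dn / g_dn2 the mirror image,
# and g_flat carries no signal. The per-class statistic ordering is thus
# unambiguous: t_A(g_up) > t_A(g_up2) > t_A(g_flat) = 0 > t_A(g_dn2) >
# t_A(g_dn), with t_B = -t_A.
toy_two_class <- function() {
  values <- rbind(
    g_up = c(5, 6, 5.5, 1, 2, 1.5),
    g_up2 = c(4, 4.5, 4.2, 2.5, 3, 2.8),
    g_dn2 = c(2.5, 3, 2.8, 4, 4.5, 4.2),
    g_dn = c(1, 2, 1.5, 5, 6, 5.5),
    g_flat = c(3, 3, 3, 3, 3, 3)
  )
  colnames(values) <- paste0("s", 1:6)
  list(expr = expression_tibble(values, scale = "log2"),
       labels = rep(c("A", "B"), each = 3))
}

small_sim <- function(n = 60, effect = 4, seed = 11, markers = 4, noise = 20) {
  sim_config(n_samples = n, marker_effect_size = effect,
             n_marker_genes_per_subtype = markers, n_noise_genes = noise,
             seed = seed)
}
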