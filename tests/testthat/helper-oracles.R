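# Independent oracle implementations used to check the package's own
# code paths. These are deliberately written from the model definitions,
# not by calling the functions they verify.

# Posterior mean E[S | O = o] under O = S + B, S ~ Exp(alpha),
# B ~ Normal(mu, sigma^2) truncated to B >= 0, by direct quadrature of
# integral s f_S(s) f_B(o - s) ds / integral f_S(s) f_B(o - s) ds over
# s in [0, o]. The truncation constant of f_B cancels in the ratio.
bg_correct_quadrature <- function(o, mu, sigma, alpha) {
  f <- function(s) stats::dexp(s, alpha) * stats::dnorm(o - s, mu, sigma)
  num <- stats::integrate(function(s) s * f(s), 0, o,
                          rel.tol = 1e-12, abs.tol = 0,
                          subdivisions = 2000L)$value
  den <- stats::integrate(f, 0, o, rel.tol = 1e-12, abs.tol = 0,
                          subdivisions = 2000L)$value
  num / den
}

# Plain loop-based median polish: alternating row/column median sweeps,
# effects re-centred to median zero, stopping when the total absolute
# residual changes by at most tol.
median_polish_oracle <- function(m, max_iter = 10L, tol = 0.01) {
  nr <- nrow(m); nc <- ncol(m)
  z <- m
  row_eff <- rep(0, nr)
  col_eff <- rep(0, nc)
  overall <- 0
  prev <- sum(abs(z))
  iters <- 0L
  converged <- FALSE
  while (iters < max_iter) {
    iters <- iters + 1L
    for (i in seq_len(nr)) {
      d <- stats::median(z[i, ])
      z[i, ] <- z[i, ] - d
      row_eff[i] <- row_eff[i] + d
    }
    d <- stats::median(col_eff)
    col_eff <- col_eff - d
    overall <- overall + d
    for (j in seq_len(nc)) {
      d <- stats::median(z[, j])
      z[, j] <- z[, j] - d
      col_eff[j] <- col_eff[j] + d
    }
    d <- stats::median(row_eff)
    row_eff <- row_eff - d
    overall <- overall + d
    tot <- sum(abs(z))
    if (tot == 0 || abs(tot - prev) <= tol) {
      converged <- TRUE
      break
    }
    prev <- tot
  }
  list(overall = overall, row_effects = row_eff, column_effects = col_eff,
       residuals = z, iterations = iters, converged = converged)
}

# Direct transcription of the moderated-t formulas.
moderated_t_oracle <- function(log2fc, s_sq, dg, n1, n2, d0, s0_sq) {
  s_tilde <- if (is.infinite(d0)) rep(s0_sq, length(s_sq)) else
    (d0 * s0_sq + dg * s_sq) / (d0 + dg)
  t <- log2fc / sqrt(s_tilde * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(t), df = d0 + dg)
  list(t_mod = t, p_value = p, s_tilde_sq = s_tilde)
}

# Brute-force top-quantile selection: type-7 interpolated quantile
# computed by hand, strict inequality at the threshold.
select_bound_oracle <- function(fold, detected, q) {
  x <- sort(fold[is.finite(fold)])
  n <- length(x)
  h <- (n - 1) * q + 1
  lo <- floor(h)
  t <- x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
  detected & is.finite(fold) & fold > t
}

# Draw variances from the scaled inverse-chi-square hierarchy:
# s^2 | sigma_g^2 ~ sigma_g^2 chisq(dg)/dg, sigma_g^2 ~ s0^2 d0/chisq(d0).
simulate_variances <- function(n, d0, s0_sq, dg) {
  sigma_g <- s0_sq * d0 / stats::rchisq(n, d0)
  sigma_g * stats::rchisq(n, dg) / dg
}

# Tiny RIP fixture on a 6-probeset platform, small enough for hand
# inspection; log2 expression values chosen directly.
tiny_annotation <- function() {
  suppressWarnings(probe_annotation(
    probe_id = paste0("p", 1:9),
    probeset_id = rep(c("ps1", "ps2", "spk1", "spk2", "spk3"),
                      c(2, 2, 2, 2, 1)),
    rna_class = rep(c("mature_miRNA", "snoRNA_CD", "spikein_control",
                      "spikein_control", "spikein_control"),
                    c(2, 2, 2, 2, 1))
  ))
}

tiny_rip_sheet <- function(cell_line = "CL1") {
  sample_sheet(
    sample_id = paste0(cell_line, c("_input", "_IP_1", "_IP_2", "_IP_3")),
    cell_line = cell_line,
    fraction = c("input", "IP", "IP", "IP"),
    treatment = "untransfected",
    replicate = c(1L, 1L, 2L, 3L)
  )
}

# Expression matrix (probesets x samples) with chosen log2 values.
tiny_expression <- function(ps1_ip = 6, ps1_input = 4,
                            ps2_ip = 5, ps2_input = 5,
                            spike = 3.5, cell_line = "CL1") {
  samples <- paste0(cell_line, c("_input", "_IP_1", "_IP_2", "_IP_3"))
  m <- rbind(
    ps1 = c(ps1_input, rep(ps1_ip, 3)),
    ps2 = c(ps2_input, rep(ps2_ip, 3)),
    spk1 = rep(spike, 4),
    spk2 = rep(spike, 4),
    spk3 = rep(spike, 4)
  )
  colnames(m) <- samples
  m
}
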