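# independent brute-force re-derivation of the heuristic likelihood,
# deliberately written as a plain per-trial loop (shared by the unit and
# acceptance suites)
brute_heuristic_nll <- function(tbl, hp, mode) {
  total <- 0
  max_dv <- max(abs(tbl$value_right[tbl$valid] - tbl$value_left[tbl$valid]))
  for (i in which(tbl$valid)) {
    vl <- tbl$value_left[i]; vr <- tbl$value_right[i]
    cat_of <- function(v) {
      if (v < hp$kappa1) "D_minus" else if (v > hp$kappa2) "D_plus"
      else "D_mid"
    }
    cl <- cat_of(vl); cr <- cat_of(vr)
    rk <- c(D_minus = 1, D_mid = 2, D_plus = 3)
    if (rk[cl] != rk[cr]) {
      forced_right <- rk[cr] > rk[cl]
      p <- if (mode == "fit") hp$p_trivial
           else plogis(hp$beta0 + hp$beta1 * max_dv)
      pc <- if ((tbl$chose_right[i] == 1) == forced_right) p else 1 - p
      total <- total - dnorm(tbl$rt[i], hp$mu_fast, hp$sigma_fast,
                             log = TRUE) - log(pc)
    } else {
      pr <- plogis(hp$beta0 + hp$beta1 * (vr - vl))
      pc <- if (tbl$chose_right[i] == 1) pr else 1 - pr
      total <- total - dnorm(tbl$rt[i], hp$mu_slow, hp$sigma_slow,
                             log = TRUE) - log(pc)
    }
  }
  total
}
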