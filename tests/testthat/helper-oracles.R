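# Independent oracles used across the suite.

# L2-star discrepancy (Warnock's closed form): measures how far a point set
# is from ideal uniformity on the unit cube
l2_star_discrepancy <- function(X) {
  n <- nrow(X)
  d <- ncol(X)
  t1 <- 3^(-d)
  t2 <- mean(apply(1 - X^2, 1, prod)) / 2^(d - 1)
  s <- 0
  for (i in seq_len(n)) {
    M <- pmax(matrix(X[i, ], n, d, byrow = TRUE), X)
    s <- s + sum(apply(1 - M, 1, prod))
  }
  sqrt(t1 - t2 + s / n^2)
}

# brute-force scalar re-evaluation of the model derivative, written term by
# term without reusing any package code path
oracle_deriv <- function(state, p) {
  y <- pmax(state, 0)
  d <- stats::setNames(numeric(11), names(state))
  anaerobic <- p[["phase"]] < 1.5
  xpao <- y[["X_PAO"]]
  if (xpao <= 0) {
    if (!anaerobic) d["S_O2"] <- p[["kla"]] * (p[["o2_sat"]] - y[["S_O2"]])
    return(d)
  }
  monod <- function(s, k) s / (s + k)
  fgly <- y[["X_Gly"]] / xpao
  fpp <- y[["X_PP"]] / xpao
  pha <- y[["X_PHB"]] + y[["X_PHV"]] + y[["X_PH2MV"]]
  fpha <- pha / xpao
  if (anaerobic || p[["vfa_gate"]] > 0.5) {
    o2g <- if (anaerobic) 1 else monod(y[["S_O2"]], p[["K_O2"]])
    avail <- monod(fgly, p[["K_Gly"]]) * monod(fpp, p[["K_PP"]])
    rac <- p[["qHAc_T"]] * monod(y[["S_HAc"]], p[["K_HAc"]]) * avail * xpao * o2g
    rpr <- p[["qHPr_T"]] * monod(y[["S_HPr"]], p[["K_HPr"]]) * avail * xpao * o2g
    d["S_HAc"] <- d["S_HAc"] - rac
    d["S_HPr"] <- d["S_HPr"] - rpr
    d["X_Gly"] <- d["X_Gly"] - p[["y_gly_ac"]] * rac - p[["y_gly_pr"]] * rpr
    d["X_PHB"] <- d["X_PHB"] + p[["y_pha_ac"]] * p[["split_ac_b"]] * rac +
      p[["y_pha_pr"]] * p[["split_pr_b"]] * rpr
    d["X_PHV"] <- d["X_PHV"] + p[["y_pha_ac"]] * p[["split_ac_v"]] * rac +
      p[["y_pha_pr"]] * p[["split_pr_v"]] * rpr
    d["X_PH2MV"] <- d["X_PH2MV"] + p[["y_pha_ac"]] * p[["split_ac_m"]] * rac +
      p[["y_pha_pr"]] * p[["split_pr_m"]] * rpr
    rel <- p[["p_rel_ac"]] * rac + p[["p_rel_pr"]] * rpr
    d["S_PO4"] <- d["S_PO4"] + rel
    d["X_PP"] <- d["X_PP"] - rel
    d["CO2"] <- d["CO2"] + p[["co2_ac"]] * rac + p[["co2_pr"]] * rpr
  }
  if (anaerobic) {
    app <- monod(y[["X_PP"]], p[["k_switch"]])
    agly <- monod(y[["X_Gly"]], p[["k_switch"]])
    mpp <- p[["mAn_T"]] * xpao * app
    g <- p[["mAn_T"]] * xpao * (1 - app) * agly / p[["gly_atp_an"]]
    d["S_PO4"] <- d["S_PO4"] + mpp
    d["X_PP"] <- d["X_PP"] - mpp
    d["X_Gly"] <- d["X_Gly"] - g
    d["X_PHB"] <- d["X_PHB"] + p[["an_maint_gly_pha"]] * g
    d["CO2"] <- d["CO2"] + (1 - p[["an_maint_gly_pha"]]) * g
    return(d)
  }
  mo2 <- monod(y[["S_O2"]], p[["K_O2"]])
  rdeg <- p[["qPHA_T"]] * monod(fpha, p[["K_fPHA"]]) * mo2 * xpao
  rgly <- p[["qGly_T"]] * monod(fpha, p[["K_PHA"]]) *
    max(0, 1 - fgly / p[["f_Gly_max"]]) * mo2 * xpao
  rpp <- p[["qPP_T"]] * monod(y[["S_PO4"]], p[["K_PO4"]]) *
    monod(fpha, p[["K_PHA"]]) * max(0, 1 - fpp / p[["f_PP_max"]]) * mo2 * xpao
  a1 <- monod(pha, p[["k_switch"]])
  a2 <- monod(y[["X_Gly"]], p[["k_switch"]])
  a3 <- monod(y[["X_PP"]], p[["k_switch"]])
  matp <- p[["mOx_T"]] * xpao * mo2
  pha_gly <- p[["y_pha_gly"]] * rgly
  pha_pp <- p[["epsilon"]] / p[["atp_per_pha"]] * rpp
  pha_mnt <- matp * a1 / p[["atp_per_pha"]]
  gly_mnt <- matp * (1 - a1) * a2 / p[["atp_per_gly"]]
  pp_mnt <- matp * (1 - a1) * (1 - a2) * a3
  rgx <- max(0, rdeg - pha_gly - pha_pp - pha_mnt)
  keff <- if (pha > 0) {
    (p[["K_1"]] * y[["X_PHB"]] + p[["K_2"]] * (y[["X_PHV"]] + y[["X_PH2MV"]])) / pha
  } else p[["K_1"]]
  ygx <- 1 / (1 + keff / p[["atp_per_pha"]])
  cons <- pha_gly + pha_pp + pha_mnt + rgx
  co2 <- (1 - ygx) * rgx + (p[["y_pha_gly"]] - 1) * rgly + pha_pp +
    pha_mnt + gly_mnt
  xb <- if (pha > 0) y[["X_PHB"]] / pha else 0
  xv <- if (pha > 0) y[["X_PHV"]] / pha else 0
  xm <- if (pha > 0) y[["X_PH2MV"]] / pha else 0
  d["X_PAO"] <- ygx * rgx
  d["X_PHB"] <- d["X_PHB"] - cons * xb
  d["X_PHV"] <- d["X_PHV"] - cons * xv
  d["X_PH2MV"] <- d["X_PH2MV"] - cons * xm
  d["X_Gly"] <- d["X_Gly"] + rgly - gly_mnt
  d["X_PP"] <- d["X_PP"] + rpp - pp_mnt
  d["S_PO4"] <- d["S_PO4"] + pp_mnt - rpp
  d["CO2"] <- d["CO2"] + co2
  d["S_O2"] <- d["S_O2"] + p[["kla"]] * (p[["o2_sat"]] - y[["S_O2"]]) -
    p[["o2_per_co2"]] * co2
  d
}

# draw a physical parameter matrix over the default database
draw_rows <- function(n, seed = 1) {
  db <- build_default_database()
  set.seed(seed)
  U <- matrix(runif(n * nrow(db)), n, nrow(db))
  transform_design(U, db)
}

# full named input row i of a parameter matrix (sampled + derived columns)
full_row <- function(pm, i) {
  c(pm$values[i, ], as.matrix(pm$derived)[i, ])
}
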