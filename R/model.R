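# The anaerobic-aerobic PAO metabolic model: 10 components, 10 kinetic
# processes, acetate/propionate stoichiometry, Arrhenius temperature and pH
# dependencies, Lanham-style sequential maintenance, Murnleitner-style
# growth on the PHA-degradation surplus.

#' Model component names
#'
#' The ten tracked components, in fixed order: dissolved oxygen, acetate,
#' propionate, orthophosphate, PAO biomass, the three PHA constituents,
#' glycogen and poly-phosphate.
#' @return Character vector of length 10.
#' @export
model_components <- function() {
  c("S_O2", "S_HAc", "S_HPr", "S_PO4", "X_PAO",
    "X_PHB", "X_PHV", "X_PH2MV", "X_Gly", "X_PP")
}

.state_names <- function() c(model_components(), "CO2")

# parameter-vector layout shared with src/pao_deriv.c
.parm_layout <- c(
  "phase", "vfa_gate",
  "qHAc_T", "qHPr_T", "mAn_T", "qPHA_T", "qGly_T", "qPP_T", "mOx_T",
  "K_HAc", "K_HPr", "K_PO4", "K_PHA", "K_Gly", "K_fPHA", "K_PP", "K_O2",
  "f_Gly_max", "f_PP_max",
  "y_gly_ac", "y_pha_ac", "co2_ac", "split_ac_b", "split_ac_v", "split_ac_m",
  "y_gly_pr", "y_pha_pr", "co2_pr", "split_pr_b", "split_pr_v", "split_pr_m",
  "p_rel_ac", "p_rel_pr",
  "atp_per_pha", "atp_per_gly", "gly_atp_an", "an_maint_gly_pha",
  "y_pha_gly", "epsilon", "K_1", "K_2",
  "kla", "o2_sat", "o2_per_co2", "k_switch"
)

#' Load and validate the model definition
#'
#' Reads the stoichiometric constants and numerical settings from a YAML
#' model-definition file and checks the elemental bookkeeping: carbon
#' entering each process must equal carbon leaving plus the CO2 entry, the
#' PHA split fractions must sum to one, and every pH-dependent yield must
#' stay within physical bounds over the validated pH range.
#'
#' @param path Path to a model YAML; defaults to the packaged definition.
#' @return A list of class `pao_model` with elements `stoichiometry` and
#'   `numerics`.
#' @examples
#' m <- pao_model()
#' m$numerics$grid_points
#' @export
pao_model <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pao_model.yaml", package = "paosens")
  }
  def <- yaml::read_yaml(path)
  st <- def$stoichiometry
  # carbon closure of the acetate column: 1 + y_gly = y_pha_total + co2
  stopifnot(abs(1 + st$hac_uptake$y_gly -
                  st$hac_uptake$y_pha_total - st$hac_uptake$co2) < 1e-9)
  stopifnot(abs(sum(st$hac_uptake$pha_split) - 1) < 1e-9,
            abs(sum(st$hpr_uptake$pha_split) - 1) < 1e-9)
  # propionate glycogen demand stays positive over the validated pH range
  for (ph in c(6, 7.5)) {
    ygly <- st$hpr_uptake$y_gly_ref + st$hpr_uptake$y_gly_ph_slope * (ph - 7)
    stopifnot(ygly > 0, 1 + ygly - st$hpr_uptake$co2 > 0)
    etr <- st$transport_atp$slope * ph + st$transport_atp$intercept
    stopifnot(etr > 0)
  }
  def$numerics$vfa_gate_tol <- def$numerics$vfa_gate_tol %||% 1e-3
  class(def) <- "pao_model"
  def
}

#' Arrhenius temperature correction of a kinetic rate
#'
#' `rate(T) = rate(T_ref) * theta^(T - T_ref)` with the reference at 20 C.
#'
#' @param rate_at_ref Positive rate at the reference temperature.
#' @param theta Positive Arrhenius temperature coefficient.
#' @param temperature Temperature in degrees C.
#' @param t_ref Reference temperature (20 C).
#' @return The corrected rate.
#' @examples
#' arrhenius_correct(1, 1.05, 30)
#' @export
arrhenius_correct <- function(rate_at_ref, theta, temperature, t_ref = 20) {
  if (any(theta <= 0)) stop("theta must be positive", call. = FALSE)
  rate_at_ref * theta^(temperature - t_ref)
}

#' pH-dependent anaerobic yields
#'
#' Resolves the pH-dependent entries of the anaerobic uptake stoichiometry
#' for one carbon source: the ATP cost of transporting the VFA across the
#' cell membrane (linear in pH), the phosphorus release per C-mol VFA (the
#' transport cost plus the activation demand, paid by poly-P hydrolysis),
#' the glycogen demand (pH-independent for acetate; weakly pH-dependent for
#' propionate), the total PHA yield that balances carbon, and the fixed
#' PHB/PHV/PH2MV split for that source.
#'
#' @param pH pH value in the validated range `[6, 7.5]`.
#' @param carbon_source `"HAc"` or `"HPr"`.
#' @param model A `pao_model`.
#' @return List with `transport_atp`, `p_release`, `y_gly`, `y_pha_total`,
#'   `co2`, `pha_split`.
#' @export
ph_yields <- function(pH, carbon_source = c("HAc", "HPr"),
                      model = pao_model()) {
  if (pH < 6 || pH > 7.5) {
    stop("pH ", pH, " outside the validated range [6, 7.5]", call. = FALSE)
  }
  carbon_source <- match.arg(carbon_source)
  st <- model$stoichiometry
  etr <- st$transport_atp$slope * pH + st$transport_atp$intercept
  p_rel <- etr + st$p_release_extra
  if (carbon_source == "HAc") {
    list(transport_atp = etr, p_release = p_rel,
         y_gly = st$hac_uptake$y_gly,
         y_pha_total = st$hac_uptake$y_pha_total,
         co2 = st$hac_uptake$co2,
         pha_split = st$hac_uptake$pha_split)
  } else {
    y_gly <- st$hpr_uptake$y_gly_ref +
      st$hpr_uptake$y_gly_ph_slope * (pH - 7)
    list(transport_atp = etr, p_release = p_rel,
         y_gly = y_gly,
         y_pha_total = 1 + y_gly - st$hpr_uptake$co2,
         co2 = st$hpr_uptake$co2,
         pha_split = st$hpr_uptake$pha_split)
  }
}

#' Resolve a sampled parameter row into simulator inputs
#'
#' Applies the Arrhenius corrections for the row's temperature, resolves the
#' pH-dependent stoichiometry and assembles (a) the numeric parameter vector
#' consumed by the compiled right-hand side and (b) the initial state built
#' from the sampled influent descriptors and intra-cellular fractions
#' (per-biomass C-mol, or P-mol for poly-P, ratios multiplied by the initial
#' biomass concentration).
#'
#' @param row Named numeric vector with the 39 sampled inputs (database
#'   names) plus the derived `S_HAc_i`, `S_HPr_i`, `S_PO4_i`.
#' @param model A `pao_model`.
#' @return List with `parms` (named, layout of the compiled model) and
#'   `init` (named state vector of length 11 including the CO2 bookkeeping
#'   pool).
#' @export
resolve_parameters <- function(row, model = pao_model()) {
  st <- model$stoichiometry
  nm <- model$numerics
  Tc <- row[["T"]]
  pH <- row[["pH"]]
  ac <- ph_yields(pH, "HAc", model)
  pr <- ph_yields(pH, "HPr", model)
  delta <- row[["delta"]]
  p <- c(
    phase = 1, vfa_gate = 0,
    qHAc_T = arrhenius_correct(row[["q_HAc"]], row[["theta_qVFA"]], Tc, nm$t_ref),
    qHPr_T = arrhenius_correct(row[["q_HPr"]], row[["theta_qVFA"]], Tc, nm$t_ref),
    mAn_T = arrhenius_correct(row[["m_ATP_an"]], row[["theta_mATP_an"]], Tc, nm$t_ref),
    qPHA_T = arrhenius_correct(row[["q_PHA"]], row[["theta_qPHA"]], Tc, nm$t_ref),
    qGly_T = arrhenius_correct(row[["q_Gly"]], row[["theta_qGly"]], Tc, nm$t_ref),
    qPP_T = arrhenius_correct(row[["q_PP"]], row[["theta_qPP"]], Tc, nm$t_ref),
    mOx_T = arrhenius_correct(row[["m_ATP_ox"]], row[["theta_mATP_ox"]], Tc, nm$t_ref),
    K_HAc = row[["K_HAc"]], K_HPr = row[["K_HPr"]], K_PO4 = row[["K_PO4"]],
    K_PHA = row[["K_PHA"]], K_Gly = row[["K_Gly"]], K_fPHA = row[["K_fPHA"]],
    K_PP = row[["K_PP"]], K_O2 = row[["K_O2"]],
    f_Gly_max = row[["f_Gly_max"]], f_PP_max = row[["f_PP_max"]],
    y_gly_ac = ac$y_gly, y_pha_ac = ac$y_pha_total, co2_ac = ac$co2,
    split_ac_b = ac$pha_split[1], split_ac_v = ac$pha_split[2],
    split_ac_m = ac$pha_split[3],
    y_gly_pr = pr$y_gly, y_pha_pr = pr$y_pha_total, co2_pr = pr$co2,
    split_pr_b = pr$pha_split[1], split_pr_v = pr$pha_split[2],
    split_pr_m = pr$pha_split[3],
    p_rel_ac = ac$p_release, p_rel_pr = pr$p_release,
    atp_per_pha = st$atp_stoich$nadh_per_pha * delta,
    atp_per_gly = st$atp_stoich$nadh_per_gly * delta,
    gly_atp_an = st$atp_stoich$gly_atp_an,
    an_maint_gly_pha = st$atp_stoich$an_maint_gly_pha,
    y_pha_gly = st$aerobic$y_pha_gly,
    epsilon = row[["epsilon"]], K_1 = row[["K_1"]], K_2 = row[["K_2"]],
    kla = st$aeration$kla, o2_sat = st$aeration$o2_sat,
    o2_per_co2 = st$o2_per_co2, k_switch = nm$k_switch
  )
  stopifnot(identical(names(p), .parm_layout))
  xpao <- row[["X_PAO_i"]]
  init <- c(
    S_O2 = 0, S_HAc = row[["S_HAc_i"]], S_HPr = row[["S_HPr_i"]],
    S_PO4 = row[["S_PO4_i"]], X_PAO = xpao,
    X_PHB = row[["w_PHB_i"]] * xpao, X_PHV = row[["w_PHV_i"]] * xpao,
    X_PH2MV = row[["w_PH2MV_i"]] * xpao,
    X_Gly = row[["f_Gly_i"]] * xpao, X_PP = row[["f_PP_i"]] * xpao,
    CO2 = 0
  )
  if (any(!is.finite(p)) || any(!is.finite(init))) {
    stop("non-finite resolved parameter or initial state", call. = FALSE)
  }
  list(parms = p, init = init)
}

# reference (plain R) evaluation of the model derivative; mirrors the
# compiled right-hand side and is exposed through the rate-law accessors
.pao_deriv_r <- function(state, parms) {
  p <- parms
  y <- pmax(state, 0)
  dy <- stats::setNames(numeric(11), .state_names())
  anaerobic <- p[["phase"]] < 1.5
  if (y[["X_PAO"]] <= 0) {
    if (!anaerobic) dy[["S_O2"]] <- p[["kla"]] * (p[["o2_sat"]] - y[["S_O2"]])
    return(dy)
  }
  xpao <- y[["X_PAO"]]
  fgly <- y[["X_Gly"]] / xpao
  fpp <- y[["X_PP"]] / xpao
  pha <- y[["X_PHB"]] + y[["X_PHV"]] + y[["X_PH2MV"]]
  fpha <- pha / xpao
  sat <- function(x, k) x / (x + k)
  ksw <- p[["k_switch"]]
  vfa_on <- anaerobic || p[["vfa_gate"]] > 0.5
  if (vfa_on) {
    gate_o2 <- if (anaerobic) 1 else sat(y[["S_O2"]], p[["K_O2"]])
    avail <- sat(fgly, p[["K_Gly"]]) * sat(fpp, p[["K_PP"]])
    r_ac <- p[["qHAc_T"]] * sat(y[["S_HAc"]], p[["K_HAc"]]) * avail * xpao * gate_o2
    r_pr <- p[["qHPr_T"]] * sat(y[["S_HPr"]], p[["K_HPr"]]) * avail * xpao * gate_o2
    dy[["S_HAc"]] <- dy[["S_HAc"]] - r_ac
    dy[["S_HPr"]] <- dy[["S_HPr"]] - r_pr
    dy[["X_Gly"]] <- dy[["X_Gly"]] - p[["y_gly_ac"]] * r_ac - p[["y_gly_pr"]] * r_pr
    dy[["X_PHB"]] <- dy[["X_PHB"]] + p[["y_pha_ac"]] * p[["split_ac_b"]] * r_ac +
      p[["y_pha_pr"]] * p[["split_pr_b"]] * r_pr
    dy[["X_PHV"]] <- dy[["X_PHV"]] + p[["y_pha_ac"]] * p[["split_ac_v"]] * r_ac +
      p[["y_pha_pr"]] * p[["split_pr_v"]] * r_pr
    dy[["X_PH2MV"]] <- dy[["X_PH2MV"]] + p[["y_pha_ac"]] * p[["split_ac_m"]] * r_ac +
      p[["y_pha_pr"]] * p[["split_pr_m"]] * r_pr
    prel <- p[["p_rel_ac"]] * r_ac + p[["p_rel_pr"]] * r_pr
    dy[["S_PO4"]] <- dy[["S_PO4"]] + prel
    dy[["X_PP"]] <- dy[["X_PP"]] - prel
    dy[["CO2"]] <- dy[["CO2"]] + p[["co2_ac"]] * r_ac + p[["co2_pr"]] * r_pr
  }
  if (anaerobic) {
    a_pp <- sat(y[["X_PP"]], ksw)
    a_gly <- sat(y[["X_Gly"]], ksw)
    m_pp <- p[["mAn_T"]] * xpao * a_pp
    g <- p[["mAn_T"]] * xpao * (1 - a_pp) * a_gly / p[["gly_atp_an"]]
    dy[["S_PO4"]] <- dy[["S_PO4"]] + m_pp
    dy[["X_PP"]] <- dy[["X_PP"]] - m_pp
    dy[["X_Gly"]] <- dy[["X_Gly"]] - g
    dy[["X_PHB"]] <- dy[["X_PHB"]] + p[["an_maint_gly_pha"]] * g
    dy[["CO2"]] <- dy[["CO2"]] + (1 - p[["an_maint_gly_pha"]]) * g
    return(dy)
  }
  mo2 <- sat(y[["S_O2"]], p[["K_O2"]])
  r_deg <- p[["qPHA_T"]] * sat(fpha, p[["K_fPHA"]]) * mo2 * xpao
  r_gly <- p[["qGly_T"]] * sat(fpha, p[["K_PHA"]]) *
    max(0, 1 - fgly / p[["f_Gly_max"]]) * mo2 * xpao
  r_pp <- p[["qPP_T"]] * sat(y[["S_PO4"]], p[["K_PO4"]]) *
    sat(fpha, p[["K_PHA"]]) * max(0, 1 - fpp / p[["f_PP_max"]]) * mo2 * xpao
  a1 <- sat(pha, ksw); a2 <- sat(y[["X_Gly"]], ksw); a3 <- sat(y[["X_PP"]], ksw)
  m_atp <- p[["mOx_T"]] * xpao * mo2
  m_pha_atp <- m_atp * a1
  m_gly_atp <- m_atp * (1 - a1) * a2
  m_pp_atp <- m_atp * (1 - a1) * (1 - a2) * a3
  pha_gly <- p[["y_pha_gly"]] * r_gly
  pha_pp <- p[["epsilon"]] / p[["atp_per_pha"]] * r_pp
  pha_mnt <- m_pha_atp / p[["atp_per_pha"]]
  gly_mnt <- m_gly_atp / p[["atp_per_gly"]]
  pp_mnt <- m_pp_atp
  r_gx <- max(0, r_deg - pha_gly - pha_pp - pha_mnt)
  k_eff <- if (pha > 0) {
    (p[["K_1"]] * y[["X_PHB"]] + p[["K_2"]] * (y[["X_PHV"]] + y[["X_PH2MV"]])) / pha
  } else p[["K_1"]]
  y_gx <- 1 / (1 + k_eff / p[["atp_per_pha"]])
  cons <- pha_gly + pha_pp + pha_mnt + r_gx
  frac <- if (pha > 0) c(y[["X_PHB"]], y[["X_PHV"]], y[["X_PH2MV"]]) / pha else c(0, 0, 0)
  co2 <- (1 - y_gx) * r_gx + (p[["y_pha_gly"]] - 1) * r_gly +
    pha_pp + pha_mnt + gly_mnt
  dy[["X_PAO"]] <- dy[["X_PAO"]] + y_gx * r_gx
  dy[["X_PHB"]] <- dy[["X_PHB"]] - cons * frac[1]
  dy[["X_PHV"]] <- dy[["X_PHV"]] - cons * frac[2]
  dy[["X_PH2MV"]] <- dy[["X_PH2MV"]] - cons * frac[3]
  dy[["X_Gly"]] <- dy[["X_Gly"]] + r_gly - gly_mnt
  dy[["X_PP"]] <- dy[["X_PP"]] + r_pp - pp_mnt
  dy[["S_PO4"]] <- dy[["S_PO4"]] + pp_mnt - r_pp
  dy[["CO2"]] <- dy[["CO2"]] + co2
  dy[["S_O2"]] <- dy[["S_O2"]] + p[["kla"]] * (p[["o2_sat"]] - y[["S_O2"]]) -
    p[["o2_per_co2"]] * co2
  dy
}

#' Process rates in the anaerobic phase
#'
#' Evaluates the anaerobic rate laws at a given state: Monod-type uptake of
#' acetate and propionate (saturating in the intra-cellular glycogen and
#' poly-P reserves, proportional to biomass), and the sequential anaerobic
#' maintenance routed through poly-P first, then glycolysis to PHB.
#'
#' @param state Named state vector (see [model_components()]; a `CO2` entry
#'   is optional).
#' @param parms Resolved parameter vector from [resolve_parameters()].
#' @return Named vector: `uptake_HAc`, `uptake_HPr`, `maint_PP` (ATP = P-mol
#'   released), `maint_Gly` (ATP drawn from glycolysis).
#' @export
anaerobic_rates <- function(state, parms) {
  state <- .as_full_state(state)
  if (any(state < 0)) stop("negative state entry", call. = FALSE)
  p <- parms
  p[["phase"]] <- 1
  y <- state
  xpao <- y[["X_PAO"]]
  if (xpao <= 0) {
    return(c(uptake_HAc = 0, uptake_HPr = 0, maint_PP = 0, maint_Gly = 0))
  }
  sat <- function(x, k) x / (x + k)
  fgly <- y[["X_Gly"]] / xpao
  fpp <- y[["X_PP"]] / xpao
  avail <- sat(fgly, p[["K_Gly"]]) * sat(fpp, p[["K_PP"]])
  a_pp <- sat(y[["X_PP"]], p[["k_switch"]])
  a_gly <- sat(y[["X_Gly"]], p[["k_switch"]])
  c(
    uptake_HAc = p[["qHAc_T"]] * sat(y[["S_HAc"]], p[["K_HAc"]]) * avail * xpao,
    uptake_HPr = p[["qHPr_T"]] * sat(y[["S_HPr"]], p[["K_HPr"]]) * avail * xpao,
    maint_PP = p[["mAn_T"]] * xpao * a_pp,
    maint_Gly = p[["mAn_T"]] * xpao * (1 - a_pp) * a_gly
  )
}

#' Process rates in the aerobic phase
#'
#' Evaluates the aerobic rate laws: PHA degradation saturating in the
#' intra-cellular PHA fraction and oxygen, glycogen and poly-P formation
#' inhibited as their per-biomass fractions approach the respective maxima,
#' sequential maintenance on PHA, then glycogen, then poly-P, and biomass
#' growth on the PHA-degradation surplus left after replenishment and
#' maintenance.  With `vfa_gate = FALSE` any residual VFA is not consumed.
#'
#' @inheritParams anaerobic_rates
#' @param vfa_gate Allow aerobic VFA uptake?
#' @return Named vector: `pha_degradation`, `gly_formation`, `pp_formation`,
#'   `maint_PHA`, `maint_Gly`, `maint_PP` (ATP rates), `growth` (biomass
#'   C-mol/l/h), `uptake_HAc`, `uptake_HPr`.
#' @export
aerobic_rates <- function(state, parms, vfa_gate = FALSE) {
  state <- .as_full_state(state)
  if (any(state < 0)) stop("negative state entry", call. = FALSE)
  p <- parms
  y <- state
  xpao <- y[["X_PAO"]]
  out <- c(pha_degradation = 0, gly_formation = 0, pp_formation = 0,
           maint_PHA = 0, maint_Gly = 0, maint_PP = 0, growth = 0,
           uptake_HAc = 0, uptake_HPr = 0)
  if (xpao <= 0) return(out)
  sat <- function(x, k) x / (x + k)
  fgly <- y[["X_Gly"]] / xpao
  fpp <- y[["X_PP"]] / xpao
  pha <- y[["X_PHB"]] + y[["X_PHV"]] + y[["X_PH2MV"]]
  fpha <- pha / xpao
  mo2 <- sat(y[["S_O2"]], p[["K_O2"]])
  r_deg <- p[["qPHA_T"]] * sat(fpha, p[["K_fPHA"]]) * mo2 * xpao
  r_gly <- p[["qGly_T"]] * sat(fpha, p[["K_PHA"]]) *
    max(0, 1 - fgly / p[["f_Gly_max"]]) * mo2 * xpao
  r_pp <- p[["qPP_T"]] * sat(y[["S_PO4"]], p[["K_PO4"]]) *
    sat(fpha, p[["K_PHA"]]) * max(0, 1 - fpp / p[["f_PP_max"]]) * mo2 * xpao
  ksw <- p[["k_switch"]]
  a1 <- sat(pha, ksw); a2 <- sat(y[["X_Gly"]], ksw); a3 <- sat(y[["X_PP"]], ksw)
  m_atp <- p[["mOx_T"]] * xpao * mo2
  pha_gly <- p[["y_pha_gly"]] * r_gly
  pha_pp <- p[["epsilon"]] / p[["atp_per_pha"]] * r_pp
  pha_mnt <- m_atp * a1 / p[["atp_per_pha"]]
  r_gx <- max(0, r_deg - pha_gly - pha_pp - pha_mnt)
  k_eff <- if (pha > 0) {
    (p[["K_1"]] * y[["X_PHB"]] + p[["K_2"]] * (y[["X_PHV"]] + y[["X_PH2MV"]])) / pha
  } else p[["K_1"]]
  out[["pha_degradation"]] <- r_deg
  out[["gly_formation"]] <- r_gly
  out[["pp_formation"]] <- r_pp
  out[["maint_PHA"]] <- m_atp * a1
  out[["maint_Gly"]] <- m_atp * (1 - a1) * a2
  out[["maint_PP"]] <- m_atp * (1 - a1) * (1 - a2) * a3
  out[["growth"]] <- r_gx / (1 + k_eff / p[["atp_per_pha"]])
  if (vfa_gate) {
    avail <- sat(fgly, p[["K_Gly"]]) * sat(fpp, p[["K_PP"]])
    out[["uptake_HAc"]] <- p[["qHAc_T"]] * sat(y[["S_HAc"]], p[["K_HAc"]]) *
      avail * xpao * mo2
    out[["uptake_HPr"]] <- p[["qHPr_T"]] * sat(y[["S_HPr"]], p[["K_HPr"]]) *
      avail * xpao * mo2
  }
  out
}

.as_full_state <- function(state) {
  full <- stats::setNames(numeric(11), .state_names())
  full[names(state)] <- state
  full
}

#' Simulate one 5-hour anaerobic-aerobic cycle
#'
#' Integrates the model over a 2.5 h anaerobic phase followed by a 2.5 h
#' aerobic phase with the compiled right-hand side (stiff-capable `lsoda`,
#' relative tolerance 1e-6, absolute tolerance 1e-9), sampling the solution
#' on a uniform grid.  Aerobic VFA uptake is disabled whenever acetate plus
#' propionate has not been depleted at the phase switch.  Reported
#' concentrations are clamped at zero; an excursion below the negativity
#' floor or a solver failure raises an error carrying the offending
#' parameter vector.
#'
#' @param init Named initial state (length 10 or 11; a missing `CO2`
#'   bookkeeping entry is added as 0).
#' @param parms Resolved parameter vector from [resolve_parameters()].
#' @param model A `pao_model` (supplies grid, tolerances, phase lengths).
#' @param grid_points Number of output times over the cycle (default from
#'   the model definition; 301 gives 1-minute resolution).
#' @return A `pao_trajectory`: tibble with `time` (h), `phase`
#'   (`"anaerobic"`/`"aerobic"`) and the 10 components plus `CO2`.
#' @examples
#' rp <- resolve_parameters(paper_scenario("fig2_fixed_ic"))
#' traj <- simulate_cycle(rp$init, rp$parms, grid_points = 51)
#' head(traj)
#' @export
simulate_cycle <- function(init, parms, model = pao_model(),
                           grid_points = NULL) {
  mat <- .simulate_cycle_matrix(.as_full_state(init), parms, model,
                                grid_points)
  phase <- ifelse(mat[, "time"] <= model$numerics$anaerobic_hours,
                  "anaerobic", "aerobic")
  out <- tibble::as_tibble(as.data.frame(mat))
  out <- dplyr::mutate(out, phase = phase, .after = "time")
  class(out) <- c("pao_trajectory", class(out))
  out
}

# fast path: returns the numeric output grid (time + 11 states), clamped
.simulate_cycle_matrix <- function(init, parms, model = pao_model(),
                                   grid_points = NULL) {
  nm <- model$numerics
  n_t <- grid_points %||% nm$grid_points
  t_an <- nm$anaerobic_hours
  t_cyc <- nm$cycle_hours
  times <- seq(0, t_cyc, length.out = n_t)
  i_switch <- which.min(abs(times - t_an))
  if (abs(times[i_switch] - t_an) > 1e-9) {
    stop("grid must contain the phase-switch time", call. = FALSE)
  }
  p1 <- parms
  p1[["phase"]] <- 1
  out1 <- .run_ode(init, times[1:i_switch], p1, nm)
  y_switch <- out1[nrow(out1), -1]
  p2 <- parms
  p2[["phase"]] <- 2
  residual_vfa <- y_switch[["S_HAc"]] + y_switch[["S_HPr"]]
  p2[["vfa_gate"]] <- as.numeric(residual_vfa <= nm$vfa_gate_tol)
  out2 <- .run_ode(y_switch, times[i_switch:n_t], p2, nm)
  full <- rbind(out1, out2[-1, , drop = FALSE])
  colnames(full) <- c("time", .state_names())
  states <- full[, -1, drop = FALSE]
  if (any(states < -1e-6)) {
    stop("state fell below the negativity floor (min ",
         format(min(states)), "); parameters: ",
         paste(names(parms), signif(parms, 6), sep = "=", collapse = ", "),
         call. = FALSE)
  }
  full[, -1] <- pmax(states, 0)
  full
}

# lsoda first; the rare corners of parameter space where its dense output
# fails are retried deterministically with the BDF-only vode solver
.run_ode <- function(y, times, parms, nm) {
  solve_with <- function(method) {
    out <- try(suppressWarnings(deSolve::ode(
      y = y, times = times, parms = parms,
      func = "pao_derivs", initfunc = "pao_initmod", dllname = "paosens",
      method = method, rtol = nm$rtol, atol = nm$atol, maxsteps = 20000
    )), silent = TRUE)
    if (inherits(out, "try-error")) return(NULL)
    if (!is.null(attr(out, "istate")) && attr(out, "istate")[1] < 0 ||
        anyNA(out)) {
      return(NULL)
    }
    out
  }
  out <- solve_with("lsoda")
  if (is.null(out)) out <- solve_with("vode")
  if (is.null(out)) {
    stop("ODE solver failed; parameters: ",
         paste(names(parms), signif(parms, 6), sep = "=", collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(out)
  colnames(m) <- c("time", names(y))
  m
}
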