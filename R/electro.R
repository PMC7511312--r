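# Single-shell membrane-charging model for a spherical cell in a uniform
# field, plus permeabilisation geometry and Joule-dose accounting for
# continuous-flow PEF treatment.

# unit conversions to SI (public interfaces use the field's customary units)
.kV_cm_to_V_m  <- function(x) x * 1e5
.mS_cm_to_S_m  <- function(x) x * 0.1
.uF_cm2_to_F_m2 <- function(x) x * 1e-2
.um_to_m       <- function(x) x * 1e-6
.ml_min_to_m3_s <- function(x) x * 1e-6 / 60
.ml_to_m3      <- function(x) x * 1e-6

#' Electrical description of a spherical cell
#'
#' Bundles the passive electrical parameters of a spherical cell that set
#' its membrane-charging time constant: radius, specific membrane
#' capacitance, and the conductivities of cytoplasm and external medium.
#' Defaults describe a *Haematococcus pluvialis* cell in low-conductivity
#' basal medium (radius 14 um, C_m 1 uF/cm2, sigma_i 10 mS/cm,
#' sigma_e 1.6 mS/cm).
#'
#' @param radius_um cell radius in micrometres (sanity bound 0.1--1000 um).
#' @param c_m_uF_cm2 membrane capacitance per unit area, uF/cm2.
#' @param sigma_i_mS_cm cytoplasm conductivity, mS/cm.
#' @param sigma_e_mS_cm external medium conductivity, mS/cm.
#'
#' @return An object of class `cell_model` storing the parameters in SI
#'   units (`a` m, `c_m` F/m2, `sigma_i`, `sigma_e` S/m) alongside the
#'   values as supplied.
#' @export
#' @examples
#' cell_model()                      # H. pluvialis defaults
#' cell_model(radius_um = 10)
cell_model <- function(radius_um = 14, c_m_uF_cm2 = 1,
                       sigma_i_mS_cm = 10, sigma_e_mS_cm = 1.6) {
  check_positive(radius_um, "radius_um")
  check_positive(c_m_uF_cm2, "c_m_uF_cm2")
  check_positive(sigma_i_mS_cm, "sigma_i_mS_cm")
  check_positive(sigma_e_mS_cm, "sigma_e_mS_cm")
  a <- .um_to_m(radius_um)
  if (a < 1e-7 || a > 1e-3) {
    abort_validation("`radius_um` outside the plausible cell range 0.1--1000 um")
  }
  structure(
    list(
      a = a,
      c_m = .uF_cm2_to_F_m2(c_m_uF_cm2),
      sigma_i = .mS_cm_to_S_m(sigma_i_mS_cm),
      sigma_e = .mS_cm_to_S_m(sigma_e_mS_cm),
      radius_um = radius_um,
      c_m_uF_cm2 = c_m_uF_cm2,
      sigma_i_mS_cm = sigma_i_mS_cm,
      sigma_e_mS_cm = sigma_e_mS_cm
    ),
    class = "cell_model"
  )
}

#' @export
print.cell_model <- function(x, ...) {
  cat("Spherical cell electrical model\n")
  cat(sprintf("  radius      : %g um\n", x$radius_um))
  cat(sprintf("  C_m         : %g uF/cm2\n", x$c_m_uF_cm2))
  cat(sprintf("  sigma_i     : %g mS/cm\n", x$sigma_i_mS_cm))
  cat(sprintf("  sigma_e     : %g mS/cm\n", x$sigma_e_mS_cm))
  cat(sprintf("  tau_C       : %.4g ns\n", charging_time_constant(x)$tau_ns))
  invisible(x)
}

#' Membrane-charging time constant and beta-dispersion frequency
#'
#' The transmembrane voltage of a spherical cell exposed to a rectangular
#' field step rises exponentially with time constant
#' \deqn{\tau_C = a C_m (1/\sigma_i + 1/(2\sigma_e)),}
#' set by the cell radius `a`, the specific membrane capacitance `C_m` and
#' the cytoplasm/medium conductivities. The characteristic frequency of
#' the beta-dispersion of the suspension is reported as `f_c = 1/tau_C`
#' (the plain reciprocal, without a `2*pi` factor).
#'
#' @param cell a [cell_model()].
#' @param field_kV_cm optional field strength (kV/cm); when supplied the
#'   steady-state polar voltage `V_pole = E*a` is included.
#'
#' @return An object of class `charging_constants`: `tau_s`, `tau_ns`,
#'   `f_c_hz`, and `v_pole_V` (NA unless `field_kV_cm` is given).
#' @export
#' @examples
#' charging_time_constant(cell_model())            # ~578 ns
#' charging_time_constant(cell_model(), 40)$v_pole_V  # 56 V
charging_time_constant <- function(cell, field_kV_cm = NULL) {
  stopifnot(inherits(cell, "cell_model"))
  tau_s <- cell$a * cell$c_m * (1 / cell$sigma_i + 1 / (2 * cell$sigma_e))
  v_pole <- NA_real_
  if (!is.null(field_kV_cm)) {
    check_positive(field_kV_cm, "field_kV_cm")
    v_pole <- .kV_cm_to_V_m(field_kV_cm) * cell$a
  }
  structure(
    list(tau_s = tau_s, tau_ns = tau_s * 1e9, f_c_hz = 1 / tau_s,
         v_pole_V = v_pole),
    class = "charging_constants"
  )
}

#' @export
print.charging_constants <- function(x, ...) {
  cat(sprintf("tau_C = %.4g ns, f_c = %.4g MHz", x$tau_ns, x$f_c_hz / 1e6))
  if (is.finite(x$v_pole_V)) cat(sprintf(", V_pole = %.4g V", x$v_pole_V))
  cat("\n")
  invisible(x)
}

.tau_ns <- function(cell, tau_ns = NULL) {
  if (is.null(tau_ns)) charging_time_constant(cell)$tau_ns else tau_ns
}

#' Transmembrane voltage at a given azimuth and time
#'
#' Induced transmembrane voltage of a spherical cell in a uniform field,
#' following the azimuthal cosine law with exponential charging:
#' \deqn{V_m(\theta, t) = E a \cos\theta (1 - e^{-t/\tau_C}).}
#' The azimuth is measured from the field-axis pole; values for
#' `theta_deg` in (90, 180] are the (negative) mirror of the opposite
#' hemisphere, i.e. `V_m(180 - theta) = -V_m(theta)`. No geometric 3/2
#' prefactor is applied by default; set `schwan_factor = 1.5` for the
#' textbook variant.
#'
#' Voltages whose magnitude exceeds `v_th` are returned unclamped but
#' flagged `hypothetical` (attribute), since above the electroporation
#' threshold the membrane is expected to break down rather than charge
#' further.
#'
#' @param cell a [cell_model()].
#' @param field_kV_cm field strength, kV/cm.
#' @param theta_deg azimuth angle(s), degrees in \[0, 180\].
#' @param t_ns time(s) since pulse onset, ns (>= 0).
#' @param v_th electroporation threshold voltage, V (default 1).
#' @param schwan_factor geometric prefactor (default 1).
#'
#' @return Numeric vector of voltages (V) with a logical attribute
#'   `hypothetical` marking entries with `|V_m| > v_th`.
#' @export
#' @examples
#' hp <- cell_model()
#' transmembrane_voltage(hp, 40, theta_deg = 0, t_ns = 25)   # ~2.37 V
transmembrane_voltage <- function(cell, field_kV_cm, theta_deg, t_ns,
                                  v_th = 1, schwan_factor = 1) {
  stopifnot(inherits(cell, "cell_model"))
  check_positive(field_kV_cm, "field_kV_cm")
  if (any(!is.finite(t_ns)) || any(t_ns < 0)) {
    abort_validation("`t_ns` must be non-negative")
  }
  if (any(!is.finite(theta_deg)) || any(theta_deg < 0) || any(theta_deg > 180)) {
    abort_validation("`theta_deg` must lie in [0, 180]")
  }
  tau <- .tau_ns(cell)
  e_si <- .kV_cm_to_V_m(field_kV_cm)
  vm <- schwan_factor * e_si * cell$a * cospi(theta_deg / 180) *
    (1 - exp(-t_ns / tau))
  attr(vm, "hypothetical") <- abs(vm) > v_th
  vm
}

#' Charging curve over azimuth and time grids
#'
#' Evaluates the transmembrane voltage on the outer product of an azimuth
#' grid and a time grid, flagging entries above the electroporation
#' threshold (the "hypothetical" band of a voltage-vs-time plot).
#'
#' @inheritParams transmembrane_voltage
#' @param theta_deg ascending azimuth grid, degrees in \[0, 90\].
#' @param t_ns ascending time grid, ns.
#'
#' @return Object of class `charging_curve`: `theta_deg`, `t_ns`, matrix
#'   `v_m` (rows = azimuth, cols = time) and logical matrix
#'   `above_threshold`. Use [as.data.frame()] for a long-format table.
#' @export
charging_curve <- function(cell, field_kV_cm, theta_deg, t_ns, v_th = 1,
                           schwan_factor = 1) {
  if (length(theta_deg) == 0L || length(t_ns) == 0L) {
    abort_validation("azimuth and time grids must be non-empty")
  }
  if (is.unsorted(theta_deg) || is.unsorted(t_ns)) {
    abort_validation("grids must be sorted ascending")
  }
  vm <- outer(theta_deg, t_ns, function(th, tt) {
    as.numeric(transmembrane_voltage(cell, field_kV_cm, th, tt,
                                     v_th = v_th, schwan_factor = schwan_factor))
  })
  dimnames(vm) <- list(theta = theta_deg, t_ns = t_ns)
  structure(
    list(theta_deg = theta_deg, t_ns = t_ns, v_m = vm,
         above_threshold = vm > v_th, v_th = v_th,
         field_kV_cm = field_kV_cm),
    class = "charging_curve"
  )
}

#' @export
as.data.frame.charging_curve <- function(x, ...) {
  data.frame(
    theta_deg = rep(x$theta_deg, times = length(x$t_ns)),
    t_ns = rep(x$t_ns, each = length(x$theta_deg)),
    v_m = as.vector(x$v_m),
    above_threshold = as.vector(x$above_threshold)
  )
}

#' Largest azimuth reaching the electroporation threshold
#'
#' Inverts the cosine charging law for the azimuth at which the
#' transmembrane voltage just reaches `v_th` at time `t_ns`:
#' `theta* = acos(v_th / (E a (1 - exp(-t/tau_C))))`. When even the pole
#' stays below threshold the threshold is unreached and `NA` is returned.
#'
#' @inheritParams transmembrane_voltage
#' @param t_ns pulse duration, ns (> 0).
#' @param tau_ns optional override of the charging time constant (ns);
#'   by default computed from `cell`.
#'
#' @return Threshold azimuth in degrees, or `NA_real_` when unreached.
#' @export
#' @examples
#' hp <- cell_model()
#' threshold_azimuth(hp, 40, t_ns = 50)  # ~77.6 degrees
#' threshold_azimuth(hp, 40, t_ns = 25)  # ~65 degrees
threshold_azimuth <- function(cell, field_kV_cm, t_ns, v_th = 1,
                              tau_ns = NULL) {
  stopifnot(inherits(cell, "cell_model"))
  check_positive(field_kV_cm, "field_kV_cm")
  check_positive(t_ns, "t_ns")
  check_positive(v_th, "v_th")
  tau <- .tau_ns(cell, tau_ns)
  v_pole <- .kV_cm_to_V_m(field_kV_cm) * cell$a * (1 - exp(-t_ns / tau))
  arg <- v_th / v_pole
  if (arg > 1) return(NA_real_)
  acos(arg) * 180 / pi
}

#' Fraction of the great-circle circumference above threshold
#'
#' A threshold azimuth `theta*` permeabilises both polar arcs of the
#' great circle through the field axis (the field polarises both
#' hemispheres), covering `c = 4 theta* / 360` of the full circumference.
#'
#' @param theta_star_deg threshold azimuth, degrees in (0, 90\].
#' @return Coverage fraction in \[0, 1\].
#' @export
#' @examples
#' circumference_coverage(90)  # 1
#' circumference_coverage(45)  # 0.5
circumference_coverage <- function(theta_star_deg) {
  if (any(!is.finite(theta_star_deg)) || any(theta_star_deg <= 0) ||
      any(theta_star_deg > 90)) {
    abort_validation("`theta_star_deg` must lie in (0, 90]")
  }
  4 * theta_star_deg / 360
}

#' Fraction of the sphere surface above threshold
#'
#' Combined area fraction of the two polar spherical caps delimited by the
#' threshold azimuth: `s = 1 - cos(theta*)` (each cap contributes
#' `(1 - cos theta*)/2` of the sphere).
#'
#' @inheritParams circumference_coverage
#' @return Surface fraction in \[0, 1\].
#' @export
#' @examples
#' sphere_cap_coverage(60)  # 0.5
sphere_cap_coverage <- function(theta_star_deg) {
  if (any(!is.finite(theta_star_deg)) || any(theta_star_deg <= 0) ||
      any(theta_star_deg > 90)) {
    abort_validation("`theta_star_deg` must lie in (0, 90]")
  }
  1 - cospi(theta_star_deg / 180)
}

#' Permeabilisation-geometry summary for one pulse duration
#'
#' @inheritParams threshold_azimuth
#' @return A one-row tibble: `t_ns`, `v_th`, `theta_star_deg`,
#'   `circumference_coverage`, `cap_coverage` (the coverages are `NA`
#'   when the threshold is unreached).
#' @export
permeabilisation_summary <- function(cell, field_kV_cm, t_ns, v_th = 1,
                                     tau_ns = NULL) {
  theta_star <- vapply(
    t_ns,
    function(tt) threshold_azimuth(cell, field_kV_cm, tt, v_th, tau_ns),
    numeric(1)
  )
  tibble(
    t_ns = t_ns,
    v_th = v_th,
    theta_star_deg = theta_star,
    circumference_coverage = ifelse(is.na(theta_star), NA_real_,
                                    4 * theta_star / 360),
    cap_coverage = ifelse(is.na(theta_star), NA_real_,
                          1 - cospi(theta_star / 180))
  )
}

#' One nsPEF treatment protocol
#'
#' Describes a pulse treatment in a continuous-flow chamber: field
#' strength, pulse duration, repetition frequency, the medium
#' conductivity, and the flow parameters that set how many pulses a cell
#' experiences during its passage. Defaults follow a 40 kV/cm treatment
#' at 4 Hz, 3.75 ml/min flow through a 0.5 ml chamber, which gives 32
#' pulses per cell.
#'
#' @param field_kV_cm field strength, kV/cm.
#' @param duration_ns pulse duration, ns.
#' @param freq_hz pulse repetition frequency, Hz (>= 0).
#' @param n_pulses number of pulses experienced per cell; if `NULL` and
#'   flow parameters are available it is derived by
#'   [residence_pulse_count()].
#' @param sigma_e_mS_cm medium conductivity, mS/cm.
#' @param flow_ml_min pump flow rate, ml/min (optional).
#' @param chamber_ml treatment-chamber volume, ml (optional; default 0.5).
#' @param rho_kg_m3 suspension mass density, kg/m3 (default 1000).
#'
#' @return Object of class `pulse_protocol`.
#' @export
#' @examples
#' pulse_protocol(duration_ns = 25)   # N = 32, the moderate treatment
pulse_protocol <- function(field_kV_cm = 40, duration_ns,
                           freq_hz = 4, n_pulses = NULL,
                           sigma_e_mS_cm = 1.6,
                           flow_ml_min = 3.75, chamber_ml = 0.5,
                           rho_kg_m3 = 1000) {
  check_positive(field_kV_cm, "field_kV_cm")
  check_positive(duration_ns, "duration_ns")
  check_positive(rho_kg_m3, "rho_kg_m3")
  check_positive(sigma_e_mS_cm, "sigma_e_mS_cm")
  if (!is.numeric(freq_hz) || length(freq_hz) != 1L || freq_hz < 0) {
    abort_validation("`freq_hz` must be a single non-negative number")
  }
  p <- structure(
    list(field_kV_cm = field_kV_cm, duration_ns = duration_ns,
         freq_hz = freq_hz, sigma_e_mS_cm = sigma_e_mS_cm,
         flow_ml_min = flow_ml_min, chamber_ml = chamber_ml,
         rho_kg_m3 = rho_kg_m3, n_pulses = n_pulses),
    class = "pulse_protocol"
  )
  if (is.null(n_pulses)) {
    p$n_pulses <- residence_pulse_count(p)
  } else {
    if (n_pulses < 0 || n_pulses != round(n_pulses)) {
      abort_validation("`n_pulses` must be a non-negative integer")
    }
  }
  p
}

#' @export
print.pulse_protocol <- function(x, ...) {
  cat(sprintf(
    "nsPEF protocol: %g kV/cm, %g ns, %g Hz, N = %d pulses, sigma_e = %g mS/cm\n",
    x$field_kV_cm, x$duration_ns, x$freq_hz, x$n_pulses, x$sigma_e_mS_cm
  ))
  invisible(x)
}

#' Average pulse count during chamber passage
#'
#' For a continuous-flow treatment chamber, the average number of pulses
#' a cell experiences is the repetition frequency times the residence
#' time: `N = round(f * V_chamber / Q)`.
#'
#' @param protocol a [pulse_protocol()] with `freq_hz`, `chamber_ml` and
#'   `flow_ml_min` set.
#' @return Integer pulse count.
#' @export
#' @examples
#' residence_pulse_count(pulse_protocol(duration_ns = 25))  # 32
residence_pulse_count <- function(protocol) {
  stopifnot(inherits(protocol, "pulse_protocol"))
  if (is.null(protocol$flow_ml_min) || is.null(protocol$chamber_ml)) {
    abort_config("flow rate and chamber volume are required to derive the pulse count")
  }
  check_positive(protocol$flow_ml_min, "flow_ml_min")
  check_positive(protocol$chamber_ml, "chamber_ml")
  q <- .ml_min_to_m3_s(protocol$flow_ml_min)
  v <- .ml_to_m3(protocol$chamber_ml)
  as.integer(round(protocol$freq_hz * v / q))
}

#' Specific treatment energy of a pulse train
#'
#' Joule heating dose of a rectangular pulse in a medium of conductivity
#' `sigma_e`: per-pulse energy density `w1 = sigma_e * E^2 * dt` (J/m3),
#' and specific treatment energy `W = N * w1 / rho` per unit suspension
#' mass. `W` is reported both in J/kg and J/g.
#'
#' @param protocol a [pulse_protocol()].
#' @return A one-row tibble of class `dose_report`: `n_pulses`,
#'   `w1_J_m3`, `W_J_kg`, `W_J_g`.
#' @export
#' @examples
#' specific_energy(pulse_protocol(duration_ns = 25))  # ~2 J/g
#' specific_energy(pulse_protocol(duration_ns = 50))  # ~4 J/g
specific_energy <- function(protocol) {
  stopifnot(inherits(protocol, "pulse_protocol"))
  e_si <- .kV_cm_to_V_m(protocol$field_kV_cm)
  w1 <- .mS_cm_to_S_m(protocol$sigma_e_mS_cm) * e_si^2 *
    protocol$duration_ns * 1e-9
  w_kg <- protocol$n_pulses * w1 / protocol$rho_kg_m3
  out <- tibble(
    n_pulses = protocol$n_pulses,
    w1_J_m3 = w1,
    W_J_kg = w_kg,
    W_J_g = w_kg / 1000
  )
  class(out) <- c("dose_report", class(out))
  out
}

#' Read an electro-model configuration file
#'
#' Reads a YAML key--value file with the model and protocol parameters in
#' customary units (`radius_um`, `c_m_uF_cm2`, `sigma_i_mS_cm`,
#' `sigma_e_mS_cm`, `field_kV_cm`, `v_th_V`, `durations_ns`, `freq_hz`,
#' `flow_ml_min`, `chamber_ml`). A default configuration is shipped in
#' `system.file("extdata", "electro_default.yaml", package = "pefastax")`.
#'
#' @param path path to the YAML file.
#' @return A list with elements `cell` ([cell_model()]), `protocols`
#'   (list of [pulse_protocol()], one per duration) and `v_th`.
#' @export
read_electro_config <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  need <- c("radius_um", "c_m_uF_cm2", "sigma_i_mS_cm", "sigma_e_mS_cm",
            "field_kV_cm", "durations_ns")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    abort_config(paste("missing config keys:", paste(missing, collapse = ", ")))
  }
  cell <- cell_model(cfg$radius_um, cfg$c_m_uF_cm2,
                     cfg$sigma_i_mS_cm, cfg$sigma_e_mS_cm)
  protocols <- lapply(cfg$durations_ns, function(d) {
    pulse_protocol(
      field_kV_cm = cfg$field_kV_cm, duration_ns = d,
      freq_hz = cfg$freq_hz %||% 4,
      sigma_e_mS_cm = cfg$sigma_e_mS_cm,
      flow_ml_min = cfg$flow_ml_min %||% 3.75,
      chamber_ml = cfg$chamber_ml %||% 0.5
    )
  })
  list(cell = cell, protocols = protocols, v_th = cfg$v_th_V %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
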