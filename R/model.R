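#' @useDynLib akinetics, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dnorm lm nlminb optim rexp rnorm runif sd setNames coef
#'   quantile vcov
#' @importFrom utils head tail modifyList
NULL

# Canonical row order of the ligand-gated chain. Asterisks count bound
# ligands; the letter part names the emission level (LID/NMP arrangement).
.AK_STATES <- c("M0", "M1", "M1*", "M", "M*",
                "M2*", "M2**", "M**", "M1**", "M3**")

.AK_GROUP <- c("M0" = "M0", "M1" = "M1", "M1*" = "M1", "M" = "M",
               "M*" = "M", "M2*" = "M2", "M2**" = "M2", "M**" = "M",
               "M1**" = "M1", "M3**" = "M3")

.AK_LID_CLOSED <- c("M2*", "M2**", "M3**")
.AK_NMP_CLOSED <- c("M1", "M1*", "M1**", "M3**")

# All elementary rate-constant names. r2/rm2 are carried in the vector but
# never placed in the generator: the chain's printed rate matrix uses only
# r1, r3 and r4 for the LID transitions.
.AK_RATE_NAMES <- c("c1", "c2", "c3", "c4", "cm1", "cm2", "cm3", "cm4",
                    "k1", "km1", "k2", "km2",
                    "b1", "bm1", "b2", "bm2",
                    "r1", "rm1", "r2", "rm2", "r3", "rm3", "r4", "rm4")

.AK_VARIANTS <- c("V1", "V2", "V3", "ADP")

#' Conformational/ligation state space of the adenylate kinase chain
#'
#' Ten states: the anomalous shallow level `M0`, the apo/liganded LID-open
#' states (`M`, `M*`, `M**`, `M1`, `M1*`, `M1**`) and the LID-closed group
#' (`M2*`, `M2**`, `M3**`). Asterisks count bound ligands; `M`/`M1`/`M2`/`M3`
#' name the observable current level (open, NMP closed, LID closed, both
#' closed). All model variants share this state space.
#'
#' @param variant One of `"V1"`, `"V2"`, `"V3"`, `"ADP"`, or an
#'   [ak_model] object.
#' @return A data.frame with one row per state (in generator row order) and
#'   columns `state`, `emission_group`, `lid_status`, `nmp_status`,
#'   `n_bound_ligands`.
#' @export
build_state_space <- function(variant = "V3") {
  if (!inherits(variant, "ak_model")) variant <- ak_model(variant)
  n_bound <- nchar(gsub("[^*]", "", .AK_STATES))
  data.frame(
    state = .AK_STATES,
    emission_group = unname(.AK_GROUP[.AK_STATES]),
    lid_status = ifelse(.AK_STATES %in% .AK_LID_CLOSED, "closed", "open"),
    nmp_status = ifelse(.AK_STATES %in% .AK_NMP_CLOSED, "closed", "open"),
    n_bound_ligands = n_bound,
    stringsAsFactors = FALSE
  )
}

#' Named vector of elementary transition rates
#'
#' Builds the full 24-element rate vector (s^-1; bimolecular association
#' constants `k1`, `k2` in s^-1 mM^-1). Unsupplied entries take the
#' package's reference values, a parameterization consistent with the
#' measured aggregate kinetics (association slope 2.2 uM^-1 s^-1, binary
#' and ternary LID opening 693.4 and ~120 s^-1, aggregate LID closing
#' ~1000 s^-1, NMP closing ~200 s^-1, and the apo NMP excursion rates).
#' `r2`/`rm2` are declared but unused by the generator.
#'
#' @param ... Named rate overrides, e.g. `rate_vector(r1 = 1000)`.
#' @return Named numeric vector over all rate-constant names.
#' @export
rate_vector <- function(...) {
  ref <- c(c1 = 50, c2 = 50, c3 = 50, c4 = 50,
           cm1 = 1, cm2 = 1, cm3 = 1, cm4 = 1,
           k1 = 4600, km1 = 2000, k2 = 2000, km2 = 200,
           b1 = 4.7, bm1 = 55.2, b2 = 200, bm2 = 3400,
           r1 = 1800, rm1 = 693.4, r2 = 1, rm2 = 1,
           r3 = 1800, rm3 = 100, r4 = 500, rm4 = 20)
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), .AK_RATE_NAMES)
    if (length(bad)) stop("unknown rate name(s): ", paste(bad, collapse = ", "))
    ref[names(ov)] <- ov
  }
  ref[.AK_RATE_NAMES]
}

#' Ligand concentration record
#'
#' @param atp_mM,amp_mM,adp_mM Concentrations in mM (non-negative).
#' @param mg Logical flag; cofactor presence is metadata only and does not
#'   enter the generator.
#' @return A list of class `ak_conc`.
#' @export
ligand_conc <- function(atp_mM = 0, amp_mM = 0, adp_mM = 0, mg = TRUE) {
  x <- list(atp_mM = atp_mM, amp_mM = amp_mM, adp_mM = adp_mM, mg = mg)
  for (f in c("atp_mM", "amp_mM", "adp_mM")) {
    v <- x[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("concentration '", f, "' must be a single non-negative number")
  }
  structure(x, class = "ak_conc")
}

.as_conc <- function(conc) {
  if (inherits(conc, "ak_conc")) return(conc)
  if (is.list(conc)) return(do.call(ligand_conc, conc))
  stop("'conc' must be an ak_conc or a named list of concentrations")
}

#' Kinetic model variant
#'
#' Constructs the structural rule set for one model variant of the
#' ligand-gated chain:
#' * `V3` - both endosteric effects: no `M* <-> M**` transition, and the
#'   LID rates of the binary (`r1`/`rm1`) and ternary (`r3`/`rm3`)
#'   complexes are free of each other.
#' * `V1` - LID dynamics independent of the second ligand: `r3`/`rm3` are
#'   tied to `r1`/`rm1` (two fewer free parameters).
#' * `V2` - second-ligand binding independent of LID status: the
#'   `M* <-> M**` transition is present with the same `k2`/`km2` rates as
#'   `M2* <-> M2**` (no new parameters).
#' * `ADP` - same topology as `V3` driven by a single ligand species: both
#'   binding steps scale with the ADP concentration.
#'
#' @param variant Variant identifier string.
#' @return An object of class `ak_model`.
#' @export
ak_model <- function(variant = "V3") {
  if (inherits(variant, "ak_model")) return(variant)
  if (!is.character(variant) || length(variant) != 1L ||
      !variant %in% .AK_VARIANTS)
    stop("unknown variant: ", paste(variant, collapse = ", "),
         " (expected one of ", paste(.AK_VARIANTS, collapse = ", "), ")")
  free <- setdiff(.AK_RATE_NAMES, c("r2", "rm2"))
  if (variant == "V1") free <- setdiff(free, c("r3", "rm3"))
  structure(list(
    variant_id = variant,
    states = .AK_STATES,
    group = .AK_GROUP,
    lid_closed = .AK_LID_CLOSED,
    nmp_closed = .AK_NMP_CLOSED,
    free = free,
    tie = function(rates) apply_variant(rates, variant),
    build_Q = function(rates, conc) .ak_build_Q(rates, conc, variant)
  ), class = "ak_model")
}

#' Custom continuous-time Markov model
#'
#' Generic container used for small test chains (e.g. a two-state
#' open/closed pore) so that the likelihood, fitting and aggregate-rate
#' machinery can be exercised independently of the ten-state enzyme model.
#'
#' @param states Character vector of state names.
#' @param group Named character vector mapping state -> emission group.
#' @param free Character vector of free rate-parameter names.
#' @param build_Q `function(rates, conc)` returning the generator (s^-1)
#'   over `states`.
#' @param lid_closed,nmp_closed States counted as closed for aggregate-rate
#'   bookkeeping.
#' @param variant_id Label.
#' @return An `ak_model`.
#' @export
make_ctmc_model <- function(states, group, free, build_Q,
                            lid_closed = character(), nmp_closed = character(),
                            variant_id = "custom") {
  stopifnot(is.character(states), length(states) >= 1L,
            all(states %in% names(group)), is.function(build_Q))
  structure(list(
    variant_id = variant_id, states = states, group = group[states],
    lid_closed = lid_closed, nmp_closed = nmp_closed, free = free,
    tie = identity, build_Q = build_Q
  ), class = "ak_model")
}

# Generator assembly for the enzyme variants. Concentrations in mM; rates
# s^-1 (k1, k2 per mM). Row order = .AK_STATES.
.ak_build_Q <- function(rates, conc, variant) {
  conc <- .as_conc(conc)
  r <- setNames(rep(NA_real_, length(.AK_RATE_NAMES)), .AK_RATE_NAMES)
  r[intersect(names(rates), .AK_RATE_NAMES)] <-
    rates[intersect(names(rates), .AK_RATE_NAMES)]
  r <- apply_variant(r, variant)
  if (variant == "ADP") {
    L1 <- conc$adp_mM
    L2 <- conc$adp_mM
  } else {
    L1 <- conc$atp_mM
    L2 <- conc$amp_mM
  }
  need <- setdiff(.AK_RATE_NAMES, c("r2", "rm2"))
  if (any(is.na(r[need]))) stop("missing required rate(s)")
  n <- length(.AK_STATES)
  Q <- matrix(0, n, n, dimnames = list(.AK_STATES, .AK_STATES))
  set <- function(from, to, rate) Q[from, to] <<- rate
  set("M0", "M1", r["c1"]);  set("M0", "M1*", r["c2"])
  set("M0", "M",  r["c3"]);  set("M0", "M*",  r["c4"])
  set("M1", "M0", r["cm1"]); set("M1", "M1*", r["k1"] * L1)
  set("M1", "M",  r["bm1"])
  set("M1*", "M0", r["cm2"]); set("M1*", "M1", r["km1"])
  set("M1*", "M*", r["bm1"])
  set("M", "M0", r["cm3"]); set("M", "M1", r["b1"])
  set("M", "M*", r["k1"] * L1)
  set("M*", "M0", r["cm4"]); set("M*", "M1*", r["b1"])
  set("M*", "M",  r["km1"]); set("M*", "M2*", r["r1"])
  set("M2*", "M*", r["rm1"]); set("M2*", "M2**", r["k2"] * L2)
  set("M2**", "M2*", r["km2"]); set("M2**", "M**", r["rm3"])
  set("M2**", "M1**", r["rm4"]); set("M2**", "M3**", r["b2"])
  set("M**", "M2**", r["r3"])
  set("M1**", "M2**", r["r4"])
  set("M3**", "M2**", r["bm2"])
  if (variant == "V2") {
    # second ligand binds regardless of LID status, with the same rates
    set("M*", "M**", r["k2"] * L2)
    set("M**", "M*", r["km2"])
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' Build the concentration-dependent CTMC generator
#'
#' Assembles the rate matrix (Q-matrix) of the chain at given ligand
#' concentrations: off-diagonal entries are elementary rate constants, the
#' two association steps scaled by ligand concentration in mM, and each
#' diagonal entry is minus the row's off-diagonal sum.
#'
#' @param rates Named rate vector (see [rate_vector()]); entries in s^-1.
#' @param conc [ligand_conc()] record (or named list).
#' @param variant Variant id or [ak_model].
#' @return Square generator matrix (s^-1) with state dimnames.
#' @export
build_generator <- function(rates = rate_vector(), conc = ligand_conc(),
                            variant = "V3") {
  model <- ak_model_of(variant)
  conc <- .as_conc(conc)
  if (any(rates[intersect(names(rates), model$free)] < 0, na.rm = TRUE))
    stop("rates must be non-negative")
  model$build_Q(rates, conc)
}

ak_model_of <- function(variant) {
  if (inherits(variant, "ak_model")) variant else ak_model(variant)
}

#' Apply a variant's parameter ties to a rate vector
#'
#' `V1` overwrites `r3 := r1` and `rm3 := rm1`; `V3`, `V2` and `ADP` are
#' identities (the `V2` rule changes topology, not parameter values). The
#' operation is idempotent.
#'
#' @inheritParams build_generator
#' @return The tied rate vector.
#' @export
apply_variant <- function(rates, variant = "V3") {
  id <- if (inherits(variant, "ak_model")) variant$variant_id else variant
  if (identical(id, "V1")) {
    rates["r3"] <- rates[["r1"]]
    rates["rm3"] <- rates[["rm1"]]
  }
  rates
}

#' Free rate parameters of a model variant
#'
#' Deterministically ordered identifiers of the independently estimated
#' rate constants: 22 for `V3`/`V2`/`ADP`, 20 for `V1` (LID ties), never
#' including the unused `r2`/`rm2`.
#'
#' @inheritParams build_generator
#' @return Character vector of parameter names.
#' @export
free_parameters <- function(variant = "V3") {
  ak_model_of(variant)$free
}

#' Serialize rates + variant to JSON
#'
#' @param rates Named rate vector (s^-1).
#' @param variant Variant id.
#' @param conc Optional [ligand_conc()].
#' @param path File path.
#' @export
write_rates_json <- function(rates, variant, path, conc = NULL) {
  obj <- list(variant_id = if (inherits(variant, "ak_model"))
    variant$variant_id else variant,
    rates_per_s = as.list(rates))
  if (!is.null(conc)) {
    conc <- .as_conc(conc)
    obj$concentrations_mM <- list(atp = conc$atp_mM, amp = conc$amp_mM,
                                  adp = conc$adp_mM)
    obj$mg_present <- conc$mg
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rates_json
#' @export
read_rates_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rates <- unlist(obj$rates_per_s)
  list(rates = rates[intersect(.AK_RATE_NAMES, names(rates))],
       variant_id = obj$variant_id,
       conc = if (!is.null(obj$concentrations_mM))
         ligand_conc(atp_mM = obj$concentrations_mM$atp,
                     amp_mM = obj$concentrations_mM$amp,
                     adp_mM = obj$concentrations_mM$adp,
                     mg = isTRUE(obj$mg_present)))
}
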