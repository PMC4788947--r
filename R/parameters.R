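#' Kinetic parameters of the reduced I1-FFL model
#'
#' Container for all kinetic constants of the reduced deterministic model of
#' the incoherent type-1 feed-forward loop, in nM and minutes, plus the
#' culture-volume triple from which the intra/extra-cellular dilution ratio
#' `K_cells` is derived.  Defaults are the published values of the reduced
#' model; the ten tunable parameters (see [decision_bounds()]) default to the
#' arithmetic midpoints of their optimization ranges so that a standalone
#' simulation is always possible.
#'
#' @param ... named overrides for any parameter field, e.g. `kd = 0.1`.
#'   Unknown names are an error.
#'
#' @return An object of class `circuit_parameters`: a named list with fields
#'   `kmA_CgA`, `kmB_CgB`, `kmC_CgC` (effective transcription capacities,
#'   nM/min), `dmA`, `dmB`, `dmC` (mRNA degradation, 1/min), `kpA`, `kpB`,
#'   `kpC` (translation, 1/min), `dA`, `dB`, `dC` (protein degradation,
#'   1/min), `kd` (inducer diffusion, 1/min), `k2`, `k3` (association,
#'   1/min), `k_2`, `k_3` (dissociation, 1/min), `dI`, `dIe` (inducer
#'   degradation, 1/min), `dAI`, `dAI2` (complex degradation, 1/min),
#'   `gamma1` (gB promoter Hill constant, nM), `gamma2` (nM), `gamma3`,
#'   `gamma4` (dimensionless), `gamma5` (1/nM), `beta1` (dimensionless),
#'   `beta2` (1/nM) promoter coefficients, and the volume triple `Vcell`
#'   (L), `Ncells` (count), `Vmedium` (L).
#' @seealso [compute_kcells()], [decision_bounds()], [expand_decision()]
#' @export
#' @examples
#' p <- circuit_parameters(kd = 0.1)
#' p$kd
circuit_parameters <- function(...) {
  mid <- function(nm) {
    b <- decision_bounds()
    unname((b$lower[b$parameter == nm] + b$upper[b$parameter == nm]) / 2)
  }
  p <- list(
    # fixed constants of the reduced model
    dmA = 0.3624, dmB = 0.3624, dmC = 0.3624,
    kpA = 80, dA = 0.035,
    kd = 0.06, k2 = 0.1, k3 = 0.1, k_2 = 20, k_3 = 1,
    gamma2 = 0.2, beta1 = 0.05, beta2 = 0.05,
    dI = 0.0164, dIe = 0.0164, dAI = 0.035, dAI2 = 0.035,
    # culture volumes defining K_cells (180 uL culture at OD 0.3)
    Vcell = 1e-15, Ncells = 2.4e8 * 0.18, Vmedium = 1.8e-4,
    # tunable parameters, defaulting to mid-bounds
    kmA_CgA = mid("kmC_CgC"),
    kmB_CgB = mid("kmB_CgB"), kmC_CgC = mid("kmC_CgC"),
    kpB = mid("kpB"), kpC = mid("kpC"),
    dB = mid("dB"), dC = mid("dC"),
    gamma1 = mid("gamma1"), gamma3 = mid("gamma3"),
    gamma4 = mid("gamma4"), gamma5 = mid("gamma5")
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(!nzchar(names(dots))))
      stop("circuit_parameters(): overrides must be named", call. = FALSE)
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("circuit_parameters(): unknown parameter(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    p[names(dots)] <- dots
  }
  validate_circuit_parameters(p)
  structure(p, class = "circuit_parameters")
}

validate_circuit_parameters <- function(p) {
  num <- vapply(p, function(v) is.numeric(v) && length(v) == 1 && is.finite(v),
                logical(1))
  if (any(!num))
    stop("circuit_parameters(): non-numeric or non-finite field(s): ",
         paste(names(p)[!num], collapse = ", "), call. = FALSE)
  pos <- setdiff(names(p), "Ncells")  # zero cells is a valid edge case
  bad <- pos[vapply(pos, function(nm) p[[nm]] <= 0, logical(1))]
  if (p$Ncells < 0) bad <- c(bad, "Ncells")
  if (length(bad))
    stop("circuit_parameters(): field(s) must be strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(p)
}

#' Intra/extracellular volume ratio K_cells
#'
#' The dilution factor relating transport of inducer between a single cell's
#' interior and the shared culture medium: `Kcells = Vcell * Ncells /
#' Vmedium`.  It scales the rate at which inducer leaving (or entering) all
#' cells changes the extracellular concentration.
#'
#' @param Vcell single-cell volume in litres (default 1e-15 L, a typical
#'   E. coli cell).
#' @param Ncells number of cells in the culture.
#' @param Vmedium culture medium volume in litres.
#' @return Dimensionless ratio `Vcell * Ncells / Vmedium`.
#' @export
#' @examples
#' compute_kcells(1e-15, 2.4e8 * 0.18, 1.8e-4)  # 2.4e-4
compute_kcells <- function(Vcell = 1e-15, Ncells = 2.4e8 * 0.18,
                           Vmedium = 1.8e-4) {
  if (!is.numeric(Vmedium) || length(Vmedium) != 1 || !is.finite(Vmedium) ||
      Vmedium <= 0)
    stop("compute_kcells(): Vmedium must be a single positive number",
         call. = FALSE)
  if (Vcell < 0 || Ncells < 0)
    stop("compute_kcells(): Vcell and Ncells must be non-negative",
         call. = FALSE)
  Vcell * Ncells / Vmedium
}

#' Bounds of the ten decision variables
#'
#' The subset of kinetic parameters selected for optimization, with the
#' initial search ranges handed to the optimizer.  These parameters map to
#' wet-lab tuning knobs: promoter strength and plasmid copy number
#' (`kmB_CgB`, `kmC_CgC`), RBS strength (`kpB`, `kpC`), degradation tags
#' (`dB`, `dC`) and promoter sequence mutations (`gamma1`, `gamma3`,
#' `gamma4`, `gamma5`).
#'
#' @return A data.frame with columns `parameter`, `lower`, `upper`, one row
#'   per decision variable, in canonical order.
#' @export
decision_bounds <- function() {
  data.frame(
    parameter = c("kmB_CgB", "kmC_CgC", "kpB", "kpC", "dB", "dC",
                  "gamma1", "gamma3", "gamma4", "gamma5"),
    lower = c(1, 1, 1, 1, 0.01, 0.01, 50, 1e-4, 5e-4, 1),
    upper = c(200, 200, 100, 100, 0.3, 0.3, 200, 0.5, 5, 100),
    stringsAsFactors = FALSE
  )
}

#' Validate a decision vector against its bounds
#'
#' @param theta named numeric vector of the ten decision variables (order
#'   free; names must match [decision_bounds()]).
#' @param tol relative slack allowed on each bound (default 0, exact).
#' @return `theta`, reordered canonically, invisibly; errors describe the
#'   offending entries.
#' @export
check_decision <- function(theta, tol = 0) {
  b <- decision_bounds()
  if (length(theta) != nrow(b))
    stop("decision vector must have length ", nrow(b), ", got ",
         length(theta), call. = FALSE)
  if (is.null(names(theta)) || !setequal(names(theta), b$parameter))
    stop("decision vector must be named with: ",
         paste(b$parameter, collapse = ", "), call. = FALSE)
  theta <- theta[b$parameter]
  slack <- tol * (b$upper - b$lower)
  bad <- which(!is.finite(theta) | theta < b$lower - slack |
                 theta > b$upper + slack)
  if (length(bad))
    stop("decision variable(s) out of bounds: ",
         paste(sprintf("%s=%g not in [%g, %g]", b$parameter[bad],
                       theta[bad], b$lower[bad], b$upper[bad]),
               collapse = "; "), call. = FALSE)
  invisible(theta)
}

#' Expand a decision vector into full circuit parameters
#'
#' Overwrites the tunable fields of a [circuit_parameters()] object with the
#' entries of `theta`.  By default the gA transcription capacity is tied to
#' the gC one (`kmA_CgA := kmC_CgC`): genes gA and gC sit on the same
#' plasmid, so they share copy number and effective capacity.
#'
#' @param theta named decision vector, see [decision_bounds()].
#' @param params base [circuit_parameters()].
#' @param tie_kmA if `TRUE` (default) set `kmA_CgA` equal to `kmC_CgC`;
#'   untie only for exploratory use.
#' @param check if `TRUE` (default) validate `theta` against its bounds.
#' @return A `circuit_parameters` object.
#' @export
expand_decision <- function(theta, params = circuit_parameters(),
                            tie_kmA = TRUE, check = TRUE) {
  if (check) theta <- check_decision(theta) else
    theta <- theta[decision_bounds()$parameter]
  params[names(theta)] <- as.list(unname(theta))
  if (tie_kmA) params$kmA_CgA <- params$kmC_CgC
  params
}

# Parameter vector for the compiled model; order must match src/i1ffl.c.
.i1ffl_parms <- function(p, load = NULL, hold_x9 = FALSE) {
  c(kmA_CgA = p$kmA_CgA, dmA = p$dmA, kpA = p$kpA, dA = p$dA,
    k2 = p$k2, k_2 = p$k_2, kd = p$kd, dI = p$dI,
    k3 = p$k3, k_3 = p$k_3, dAI = p$dAI, dAI2 = p$dAI2,
    kmB_CgB = p$kmB_CgB, gamma1 = p$gamma1, dmB = p$dmB,
    kpB = p$kpB, dB = p$dB,
    kmC_CgC = p$kmC_CgC, gamma2 = p$gamma2, gamma3 = p$gamma3,
    gamma4 = p$gamma4, gamma5 = p$gamma5,
    beta1 = p$beta1, beta2 = p$beta2,
    dmC = p$dmC, kpC = p$kpC, dC = p$dC,
    Kcells = compute_kcells(p$Vcell, p$Ncells, p$Vmedium), dIe = p$dIe,
    K1 = if (is.null(load)) 0 else load$K1,
    K2 = if (is.null(load)) 0 else load$K2,
    hold_x9 = as.numeric(hold_x9))
}

#' Downstream binding-load parameters
#'
#' A minimal retroactivity model: the output protein C binds reversibly to a
#' conserved pool of downstream sites (e.g. promoter regions), `C + L <->
#' C.L`, sequestering C without degrading it.
#'
#' @param K1 binding rate (1/nM/min; default 40, mildly fast binding).
#' @param K2 unbinding rate (1/min; default 20).
#' @param LT total load species (nM; default 800).
#' @return An object of class `load_parameters`.
#' @export
load_parameters <- function(K1 = 40, K2 = 20, LT = 800) {
  if (!is.finite(K1) || K1 <= 0 || !is.finite(K2) || K2 <= 0)
    stop("load_parameters(): K1 and K2 must be positive", call. = FALSE)
  if (!is.finite(LT) || LT < 0)
    stop("load_parameters(): LT must be non-negative", call. = FALSE)
  structure(list(K1 = K1, K2 = K2, LT = LT), class = "load_parameters")
}
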