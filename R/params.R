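#' Kinetic and volume parameters of the losartan/E-3174 model
#'
#' Constructs the full parameter set of the five-compartment model: gastric
#' valve amplitude/period, intestinal and enterocyte transfer rates (the
#' enterocyte-to-intestine rate `k_ent_int` is the ABCB1 efflux activity),
#' the delayed CYP2C9 conversion rate `k_m` with delay `T`, and the apparent
#' clearances/volumes of losartan (central + peripheral) and its metabolite.
#'
#' Defaults describe a wild-type (CYP2C9*1/*1, ABCB1 GG/CC) adult after a
#' single oral dose. The disposition parameters (`CL_p`, `Vp_1`, `CL_m`,
#' `Vm`) are calibrated so that a 50 mg dose yields a losartan exposure of
#' about 1.35e3 nmol·h/L (apparent oral clearance ~80 L/h) and a metabolite
#' exposure of about 7.7e3 nmol·h/L with a terminal metabolite half-life
#' near 4 h, the magnitudes reported clinically for wild-type Korean
#' subjects. Absorption-side values are chosen for physiological
#' plausibility (gastric emptying on the 1 h scale, rapid enterocyte
#' exchange); see the package vignette.
#'
#' @param a Gastric-valve amplitude (1/h, > 0).
#' @param b Gastric-valve period (h, > 0).
#' @param k_int_ent Intestine-to-enterocyte absorption rate (1/h, >= 0).
#' @param k_ent_int Enterocyte-to-intestine ABCB1 efflux rate (1/h, >= 0).
#' @param k_ent_cc Enterocyte-to-central absorption rate (1/h, >= 0).
#' @param k_m Losartan-to-E-3174 conversion rate (1/h, >= 0), the CYP2C9
#'   activity.
#' @param T Conversion time delay (h, >= 0).
#' @param CL_m Apparent E-3174 clearance (L/h, > 0).
#' @param Vm Apparent E-3174 distribution volume (L, > 0).
#' @param CL_p Apparent losartan clearance (L/h, > 0).
#' @param Vp_1 Apparent central losartan volume (L, > 0).
#' @param Q Central-peripheral inter-compartment clearance (L/h, >= 0).
#' @param Vp_2 Apparent peripheral losartan volume (L, > 0).
#' @param k_int_ex Optional first-order intestinal loss rate (1/h, >= 0,
#'   default 0: no luminal loss, the model's default mass-closed absorption
#'   loop).
#' @param valve Functional form of the gastric emptying rate:
#'   `"sinusoidal"` (default) for `a*(1+sin(2*pi*t/b))/2`, or `"constant"`
#'   for a fixed rate `a` (used e.g. for closed-form checks).
#'
#' @return An object of class `losartan_params` (a named list).
#' @seealso [simulate_losartan()], [genotype_params()], [read_params()]
#' @export
#' @examples
#' p <- losartan_params()
#' p$k_m
#' losartan_params(k_m = 0.039)  # a poor-metabolizer CYP2C9 activity
losartan_params <- function(a = 1.5, b = 1, k_int_ent = 1.5,
                            k_ent_int = 151.485, k_ent_cc = 40,
                            k_m = 2.817, T = 0.5,
                            CL_m = 6.373, Vm = 37.7,
                            CL_p = 43.867, Vp_1 = 12.966,
                            Q = 2, Vp_2 = 20,
                            k_int_ex = 0,
                            valve = c("sinusoidal", "constant")) {
  valve <- match.arg(valve)
  p <- list(a = a, b = b, k_int_ent = k_int_ent, k_ent_int = k_ent_int,
            k_ent_cc = k_ent_cc, k_m = k_m, T = T, CL_m = CL_m, Vm = Vm,
            CL_p = CL_p, Vp_1 = Vp_1, Q = Q, Vp_2 = Vp_2,
            k_int_ex = k_int_ex, valve = valve)
  validate_params(p)
  class(p) <- "losartan_params"
  p
}

# Names of the 13 kinetic/volume parameters (serialization order).
PARAM_NAMES <- c("a", "b", "k_int_ent", "k_ent_int", "k_ent_cc", "k_m", "T",
                 "CL_m", "Vm", "CL_p", "Vp_1", "Q", "Vp_2")

validate_params <- function(p) {
  num <- c(PARAM_NAMES, "k_int_ex")
  for (nm in num) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number",
           call. = FALSE)
  }
  pos <- c("a", "b", "CL_m", "Vm", "CL_p", "Vp_1", "Vp_2")
  for (nm in pos)
    if (p[[nm]] <= 0)
      stop("parameter '", nm, "' must be strictly positive", call. = FALSE)
  nn <- c("k_int_ent", "k_ent_int", "k_ent_cc", "k_m", "T", "Q", "k_int_ex")
  for (nm in nn)
    if (p[[nm]] < 0)
      stop("parameter '", nm, "' must be nonnegative", call. = FALSE)
  invisible(p)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named values replaced, re-validated.
#'
#' @param params A [losartan_params()] object.
#' @param ... Named scalar replacements, e.g. `k_m = 0.039`.
#' @return A `losartan_params` object.
#' @export
set_params <- function(params, ...) {
  stopifnot(inherits(params, "losartan_params"))
  repl <- list(...)
  if (length(repl)) {
    bad <- setdiff(names(repl), c(PARAM_NAMES, "k_int_ex", "valve"))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    params[names(repl)] <- repl
  }
  validate_params(params)
  params
}

#' @export
print.losartan_params <- function(x, ...) {
  cat("Losartan/E-3174 model parameters\n")
  v <- unlist(x[PARAM_NAMES])
  units <- c(a = "1/h", b = "h", k_int_ent = "1/h", k_ent_int = "1/h",
             k_ent_cc = "1/h", k_m = "1/h", T = "h", CL_m = "L/h",
             Vm = "L", CL_p = "L/h", Vp_1 = "L", Q = "L/h", Vp_2 = "L")
  for (nm in PARAM_NAMES)
    cat(sprintf("  %-10s %12.6g  %s\n", nm, v[[nm]], units[[nm]]))
  if (x$k_int_ex > 0)
    cat(sprintf("  %-10s %12.6g  1/h (intestinal loss)\n", "k_int_ex",
                x$k_int_ex))
  cat("  gastric valve:", x$valve, "\n")
  invisible(x)
}

#' @export
as.data.frame.losartan_params <- function(x, ...) {
  data.frame(parameter = PARAM_NAMES,
             value = unname(unlist(x[PARAM_NAMES])),
             stringsAsFactors = FALSE)
}

#' Read and write model parameter files
#'
#' Parameters are stored as a flat key-to-value map (JSON or YAML), keyed by
#' the canonical parameter symbols `a, b, k_int_ent, k_ent_int, k_ent_cc,
#' k_m, T, CL_m, Vm, CL_p, Vp_1, Q, Vp_2` (plus the optional `k_int_ex` and
#' `valve` entries). The round trip `read_params(write_params(p))` is
#' lossless.
#'
#' @param params A [losartan_params()] object.
#' @param path File path; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @return `read_params()` returns a `losartan_params` object;
#'   `write_params()` returns `path` invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "losartan_params"))
  x <- params[c(PARAM_NAMES, "k_int_ex", "valve")]
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path, precision = 17L)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  missing <- setdiff(PARAM_NAMES, names(x))
  if (length(missing))
    stop("parameter file lacks key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  args <- x[intersect(names(x), c(PARAM_NAMES, "k_int_ex", "valve"))]
  do.call(losartan_params, args)
}
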