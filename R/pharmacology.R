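#' Single-pore-channel conductance block factor
#'
#' `G_i = G_0 / (1 + [C_d] / IC50)`: the factor returned is `G_i / G_0`,
#' in (0, 1], strictly decreasing in the concentration, and equal to 0.5 at
#' the IC50 by definition. Scale-invariant: multiplying concentration and
#' IC50 by the same constant leaves the factor unchanged.
#'
#' @param concentration drug concentration (uM), >= 0 (vectorised).
#' @param ic50 half-inhibitory concentration (uM), > 0.
#' @return Dimensionless conductance factor.
#' @export
block_factor <- function(concentration, ic50) {
  if (any(concentration < 0)) stop("negative drug concentration")
  if (any(ic50 <= 0)) stop("IC50 must be positive")
  1 / (1 + concentration / ic50)
}

#' Antiarrhythmic drug specifications
#'
#' The shipped drug library (amiodarone, dofetilide, sotalol) gives each
#' drug's simulated plasma concentration and its IC50 for the three targeted
#' myocyte channels (IKr, ICaL, INa); fibroblast currents are untouched.
#'
#' @param name drug name (case-insensitive) or `"none"`.
#' @return List of class `drug_spec` with `name`, `concentration` (uM) and
#'   `ic50` (named vector, uM), or `NULL` for `"none"`.
#' @export
drug_spec <- function(name) {
  if (is.null(name) || tolower(name) == "none") return(NULL)
  lib <- drug_library()
  i <- match(tolower(name), tolower(vapply(lib, `[[`, "", "name")))
  if (is.na(i)) stop("unknown drug: ", name)
  lib[[i]]
}

#' @rdname drug_spec
#' @export
drug_library <- function() {
  raw <- jsonlite::read_json(system.file("extdata", "drugs.json",
                                         package = "atriasim"),
                             simplifyVector = FALSE)
  lapply(raw, function(d) {
    ic50 <- unlist(d$ic50)
    stopifnot(all(names(ic50) %in% c("IKr", "ICaL", "INa")), all(ic50 > 0),
              d$concentration >= 0)
    structure(list(name = d$name, concentration = d$concentration, ic50 = ic50),
              class = "drug_spec")
  })
}

#' @export
print.drug_spec <- function(x, ...) {
  cat(sprintf("<drug_spec: %s, [C_d] = %g uM; IC50 (uM): %s>\n", x$name,
              x$concentration,
              paste(names(x$ic50), signif(x$ic50, 4), sep = "=", collapse = ", ")))
  invisible(x)
}

## channel -> myocyte parameter receiving the block factor (kept as data for
## auditability)
drug_channel_map <- c(IKr = "g_Kr", ICaL = "g_CaL", INa = "g_Na")

#' Per-channel block factors for a drug
#'
#' @param drug a `drug_spec` or `NULL`.
#' @return Named vector of `G_i / G_0` factors for IKr, ICaL, INa (all 1 for
#'   no drug).
#' @export
drug_factors <- function(drug) {
  if (is.null(drug)) return(c(IKr = 1, ICaL = 1, INa = 1))
  f <- vapply(c("IKr", "ICaL", "INa"),
              function(ch) block_factor(drug$concentration, drug$ic50[[ch]]),
              numeric(1))
  stats::setNames(f, c("IKr", "ICaL", "INa"))
}

#' Apply pore-block drug effects to myocyte parameters
#'
#' Multiplies the rapid delayed-rectifier, L-type Ca2+ and fast Na+
#' conductances by their respective block factors. Composition with profile
#' scaling is order-independent (both are multiplicative). Drugs act on
#' myocyte channels only.
#'
#' @param params myocyte `cell_parameters` (typically already profile-scaled).
#' @param drug a `drug_spec` or `NULL` (identity).
#' @return Modified parameters; no conductance is ever increased.
#' @export
apply_drug <- function(params, drug) {
  if (is.null(drug)) return(params)
  f <- drug_factors(drug)
  for (ch in names(f)) {
    tgt <- drug_channel_map[[ch]]
    params[[tgt]] <- params[[tgt]] * f[[ch]]
  }
  params
}
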