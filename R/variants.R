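# Per-region model variants: conductance scalings, Na+ inactivation shift,
# ACh concentration and remodeling flags applied on top of the base atrial
# cell model.

#' Create a model variant
#'
#' A variant captures every regional / pharmacological modification applied
#' to the base atrial cell model: multiplicative conductance scalings, a
#' depolarizing shift of the Na+ steady-state inactivation curves, the local
#' acetylcholine concentration, and flags for AF electrical remodeling.
#'
#' @param region `"LA"` or `"PV"`.
#' @param gCaL_scale,gNCX_scale,gK1_scale,gto_scale,gKur_scale,gKr_scale,gKs_scale
#'   dimensionless multipliers (> 0, default 1).
#' @param INa_inact_shift shift of the h/j steady-state inactivation curves
#'   (mV, positive = depolarized; widens the Na+ window and delays
#'   inactivation-gate closing).
#' @param ACh acetylcholine concentration (uM, >= 0).
#' @param rel_scale,leak_scale multipliers on the SR release and leak fluxes.
#' @param remodeled logical, set by [apply_af_remodeling()].
#' @return An object of class `model_variant`.
#' @export
model_variant <- function(region = "LA",
                          gCaL_scale = 1, gNCX_scale = 1, gK1_scale = 1,
                          gto_scale = 1, gKur_scale = 1, gKr_scale = 1,
                          gKs_scale = 1, INa_inact_shift = 0, ACh = 0,
                          rel_scale = 1, leak_scale = 1, remodeled = FALSE) {
  region <- match.arg(region, c("LA", "PV"))
  v <- list(region = region, gCaL_scale = gCaL_scale, gNCX_scale = gNCX_scale,
            gK1_scale = gK1_scale, gto_scale = gto_scale,
            gKur_scale = gKur_scale, gKr_scale = gKr_scale,
            gKs_scale = gKs_scale, INa_inact_shift = INa_inact_shift,
            ACh = ACh, rel_scale = rel_scale, leak_scale = leak_scale,
            remodeled = isTRUE(remodeled))
  sc <- unlist(v[grep("_scale$", names(v))])
  if (any(!is.finite(sc)) || any(sc <= 0))
    stop("all conductance/flux scalings must be finite and > 0")
  if (!is.finite(v$ACh) || v$ACh < 0) stop("ACh must be >= 0")
  class(v) <- "model_variant"
  v
}

#' @export
print.model_variant <- function(x, ...) {
  sc <- unlist(x[grep("_scale$", names(x))])
  mod <- sc[abs(sc - 1) > 1e-12]
  cat("<model_variant> region=", x$region,
      if (x$remodeled) " [AF-remodeled]" else "", "\n", sep = "")
  if (length(mod))
    cat("  scalings:", paste(names(mod), signif(mod, 4), sep = "=", collapse = ", "), "\n")
  if (x$INa_inact_shift != 0)
    cat("  INa inactivation shift:", x$INa_inact_shift, "mV\n")
  cat("  ACh:", x$ACh, "uM\n")
  invisible(x)
}

# Default pulmonary-vein current-scaling table: reduced inward rectifier,
# transient outward and L-type Ca2+ conductances, augmented delayed
# rectifiers, as reported for PV sleeve cardiomyocytes. User-overridable via
# options(atriagp.pv_factors = list(...)).
.pv_factors_default <- list(gK1_scale = 0.7, gto_scale = 0.75,
                            gCaL_scale = 0.7, gKr_scale = 1.6,
                            gKs_scale = 1.6)

#' Pulmonary-vein current-scaling table
#'
#' Returns the named list of multiplicative factors that convert an LA
#' variant into a PV variant. The defaults shorten the PV action potential
#' relative to the LA at slow rates. Override globally with
#' `options(atriagp.pv_factors = list(...))`.
#'
#' @return Named list of scaling factors.
#' @export
pv_factors <- function() {
  ov <- getOption("atriagp.pv_factors", NULL)
  f <- .pv_factors_default
  if (!is.null(ov)) f[names(ov)] <- ov
  f
}

#' Convert a variant to its pulmonary-vein form
#'
#' Sets `region = "PV"` and applies the PV current-scaling table
#' ([pv_factors()]) once. Idempotent: applying it to a variant already in PV
#' form is a no-op.
#'
#' @param variant a [model_variant()].
#' @param factors optional override of the scaling table.
#' @return The PV variant.
#' @export
apply_pv_variant <- function(variant, factors = pv_factors()) {
  if (variant$region == "PV") return(variant)
  for (nm in names(factors)) variant[[nm]] <- variant[[nm]] * factors[[nm]]
  variant$region <- "PV"
  variant
}

#' Apply chronic AF electrical remodeling
#'
#' Multiplies the existing scalings by the remodeling set used to sustain
#' fibrillation: IK1 x1.5, Ito x0.2, ICaL x0.6, IKur x0.5, and flags the
#' variant as remodeled. Composes multiplicatively with prior scalings.
#'
#' @param variant a [model_variant()].
#' @return The remodeled variant.
#' @export
apply_af_remodeling <- function(variant) {
  variant$gK1_scale <- variant$gK1_scale * 1.5
  variant$gto_scale <- variant$gto_scale * 0.2
  variant$gCaL_scale <- variant$gCaL_scale * 0.6
  variant$gKur_scale <- variant$gKur_scale * 0.5
  variant$remodeled <- TRUE
  variant
}

#' Apply autonomic (sympathetic + parasympathetic) stimulation
#'
#' Sets the combined autonomic modification: ACh concentration
#' (parasympathetic, activates IKACh), an ICaL fold increase (sympathetic
#' beta-adrenergic effect), an NCX fold increase, and a depolarizing shift of
#' the Na+ inactivation curve. Defaults correspond to the combined
#' stimulation condition that elicits late phase 3 EAD-like activity.
#'
#' @param variant a [model_variant()].
#' @param ACh acetylcholine concentration (uM).
#' @param ical_fold multiplier on ICaL conductance.
#' @param ncx_fold multiplier on the Na+/Ca2+ exchanger current.
#' @param ina_shift_mV depolarizing shift of h/j steady-state inactivation (mV).
#' @return The modified variant.
#' @export
apply_ans_stimulation <- function(variant, ACh = 0.05, ical_fold = 7,
                                  ncx_fold = 2, ina_shift_mV = 10) {
  variant$ACh <- ACh
  variant$gCaL_scale <- variant$gCaL_scale * ical_fold
  variant$gNCX_scale <- variant$gNCX_scale * ncx_fold
  variant$INa_inact_shift <- variant$INa_inact_shift + ina_shift_mV
  variant
}

#' Registry of named model variants
#'
#' @param name one of `"control"`, `"pv"`, `"ans_ead"` (PV cell under the
#'   combined autonomic condition used in the 2D sheet), `"af_remodeled"`,
#'   `"af_remodeled+gp"` (remodeled, ACh applied per-node by the GP layout).
#' @return A [model_variant()].
#' @export
variant_registry <- function(name) {
  switch(match.arg(name, c("control", "pv", "ans_ead", "af_remodeled",
                           "af_remodeled+gp")),
    control = model_variant(),
    pv = apply_pv_variant(model_variant()),
    ans_ead = apply_ans_stimulation(apply_pv_variant(model_variant())),
    af_remodeled = apply_af_remodeling(model_variant()),
    `af_remodeled+gp` = apply_af_remodeling(model_variant())
  )
}

#' Serialize / deserialize variants as YAML
#'
#' @param variant a [model_variant()].
#' @param path file path; if `NULL`, the YAML string is returned.
#' @return `variant_to_yaml`: path or YAML string; `variant_from_yaml`: a
#'   [model_variant()].
#' @export
variant_to_yaml <- function(variant, path = NULL) {
  x <- unclass(variant)
  if (is.null(path)) return(yaml::as.yaml(x))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname variant_to_yaml
#' @param text YAML string (alternative to `path`).
#' @export
variant_from_yaml <- function(path = NULL, text = NULL) {
  x <- if (is.null(text)) yaml::read_yaml(path) else yaml::yaml.load(text)
  do.call(model_variant, x)
}
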