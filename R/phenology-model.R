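#' Stage-level and whole-insect phenology models
#'
#' A `stage_model` ties the temperature-response curves of one life stage
#' together. Immature stages (egg, larva, pupa) carry a development-rate
#' curve, a U-shaped mortality curve and a normalized development-time
#' distribution; adult stages carry a senescence (aging-rate) curve and a
#' longevity distribution over normalized senescence age.
#'
#' @param stage One of `"egg"`, `"larva"`, `"pupa"`, `"adult_female"`,
#'   `"adult_male"`.
#' @param devtime_dist [fn_spec()] with family `cll_devtime` or
#'   `logit_devtime`.
#' @param dev_rate [fn_spec()] of a rate family (immature stages only).
#' @param mortality [fn_spec()] with family `wang_mortality_1`
#'   (immature stages only).
#' @param senescence [fn_spec()] with family `exp_simple_senescence`
#'   (adult stages only).
#' @return An object of class `stage_model`.
#' @export
stage_model <- function(stage, devtime_dist, dev_rate = NULL,
                        mortality = NULL, senescence = NULL) {
  stage <- match.arg(stage, c("egg", "larva", "pupa", "adult_female",
                              "adult_male"))
  .assert_kind(devtime_dist, "devtime", "stage_model")
  immature <- stage %in% c("egg", "larva", "pupa")
  if (immature) {
    if (is.null(dev_rate) || is.null(mortality)) {
      abort(sprintf("immature stage '%s' needs dev_rate and mortality", stage))
    }
    .assert_kind(dev_rate, "rate", "stage_model")
    .assert_kind(mortality, "mortality", "stage_model")
    if (!is.null(senescence)) abort("immature stages carry no senescence curve")
  } else {
    if (is.null(senescence)) {
      abort(sprintf("adult stage '%s' needs a senescence curve", stage))
    }
    .assert_kind(senescence, "senescence", "stage_model")
    if (!is.null(dev_rate) || !is.null(mortality)) {
      abort("adult stages carry senescence only, not dev_rate/mortality")
    }
  }
  structure(list(stage = stage, devtime_dist = devtime_dist,
                 dev_rate = dev_rate, mortality = mortality,
                 senescence = senescence),
            class = "stage_model")
}

#' @rdname stage_model
#' @param stages List of `stage_model`s covering egg, larva, pupa,
#'   adult_female and adult_male (in that life-cycle order).
#' @param fecundity_mean [fn_spec()] with family `taylor_fecundity_1`
#'   (lifetime eggs per female vs temperature).
#' @param fecundity_cum [fn_spec()] with family `exp_modified_cumfec_3`
#'   (fraction of eggs laid by normalized female age).
#' @param sex_ratio Proportion of offspring that are female, in `(0, 1)`.
#' @return `phenology_model()` returns an object of class
#'   `phenology_model`.
#' @export
phenology_model <- function(stages, fecundity_mean, fecundity_cum,
                            sex_ratio = 0.5) {
  order <- c("egg", "larva", "pupa", "adult_female", "adult_male")
  names(stages) <- vapply(stages, function(s) s$stage, character(1))
  missing <- setdiff(order, names(stages))
  if (length(missing) > 0) {
    abort(paste("phenology_model: missing stage(s):",
                paste(missing, collapse = ", ")))
  }
  stages <- stages[order]
  .assert_kind(fecundity_mean, "fecundity", "phenology_model")
  .assert_kind(fecundity_cum, "cumfec", "phenology_model")
  if (!(sex_ratio > 0 && sex_ratio < 1)) abort("sex_ratio must be in (0, 1)")
  structure(list(stages = stages, fecundity_mean = fecundity_mean,
                 fecundity_cum = fecundity_cum, sex_ratio = sex_ratio),
            class = "phenology_model")
}

immature_stages <- function(model) model$stages[c("egg", "larva", "pupa")]

#' @export
print.phenology_model <- function(x, ...) {
  cat("<phenology_model>\n")
  for (s in x$stages) {
    parts <- c(
      sprintf("devtime=%s", s$devtime_dist$family),
      if (!is.null(s$dev_rate)) sprintf("rate=%s", s$dev_rate$family),
      if (!is.null(s$mortality)) sprintf("mortality=%s", s$mortality$family),
      if (!is.null(s$senescence)) sprintf("senescence=%s", s$senescence$family)
    )
    cat(sprintf("  %-12s %s\n", s$stage, paste(parts, collapse = ", ")))
  }
  cat(sprintf("  fecundity: mean=%s, cumulative=%s, sex_ratio=%.2f\n",
              x$fecundity_mean$family, x$fecundity_cum$family, x$sex_ratio))
  invisible(x)
}

fn_spec_to_list <- function(spec) {
  list(family = spec$family, params = spec$params,
       temp_domain = as.numeric(spec$temp_domain))
}

fn_spec_from_list <- function(lst) {
  fn_spec(lst$family, lst$params, temp_domain = unlist(lst$temp_domain))
}

#' Read and write phenology models as YAML parameter files
#'
#' The on-disk format stores, per stage, each curve as
#' `{family, params, temp_domain}`, plus the two fecundity curves and the
#' sex ratio — a plain-text parameter file that round-trips exactly.
#'
#' @param model A [phenology_model()].
#' @param path File path of the YAML parameter file.
#' @return `read_phenology_model()` returns a [phenology_model()];
#'   `write_phenology_model()` returns `path` invisibly.
#' @export
write_phenology_model <- function(model, path) {
  stopifnot(inherits(model, "phenology_model"))
  out <- list(
    stages = lapply(model$stages, function(s) {
      l <- list(stage = s$stage,
                devtime_dist = fn_spec_to_list(s$devtime_dist))
      if (!is.null(s$dev_rate)) l$dev_rate <- fn_spec_to_list(s$dev_rate)
      if (!is.null(s$mortality)) l$mortality <- fn_spec_to_list(s$mortality)
      if (!is.null(s$senescence)) l$senescence <- fn_spec_to_list(s$senescence)
      l
    }),
    fecundity_mean = fn_spec_to_list(model$fecundity_mean),
    fecundity_cum = fn_spec_to_list(model$fecundity_cum),
    sex_ratio = model$sex_ratio
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname write_phenology_model
#' @export
read_phenology_model <- function(path) {
  raw <- yaml::read_yaml(path)
  stages <- lapply(raw$stages, function(s) {
    stage_model(
      stage = s$stage,
      devtime_dist = fn_spec_from_list(s$devtime_dist),
      dev_rate = if (!is.null(s$dev_rate)) fn_spec_from_list(s$dev_rate),
      mortality = if (!is.null(s$mortality)) fn_spec_from_list(s$mortality),
      senescence = if (!is.null(s$senescence)) fn_spec_from_list(s$senescence)
    )
  })
  phenology_model(stages,
                  fecundity_mean = fn_spec_from_list(raw$fecundity_mean),
                  fecundity_cum = fn_spec_from_list(raw$fecundity_cum),
                  sex_ratio = raw$sex_ratio)
}
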