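#' Construct a covariance-structure model as an explicit parameter map
#'
#' A `sem_model` lists every variable (observed or latent) and every path of
#' the model.  Directed paths carry regression/loading coefficients;
#' `covariance` paths carry (co)variances, with `source == target` denoting a
#' variance (an exogenous variance or an endogenous disturbance).  Each path
#' is either `fixed` at a value or `free` with a parameter label.  Measurement
#' error variances of observed indicators are not listed as paths: they are
#' fixed at `error_fraction * sample variance` of the indicator, resolved once
#' from the moment set when the model is fitted (the fixed-reliability
#' construction, error fraction = 1 - reliability).
#'
#' @param variables data frame with columns `name`, `kind`
#'   (`"observed"`/`"latent"`) and optionally `role` (free-text tag).
#' @param paths data frame with columns `source`, `target`, `kind`
#'   (`"directed"`/`"covariance"`), `status` (`"fixed"`/`"free"`), `value`
#'   (required for fixed paths), `label` (required for free paths), and
#'   optionally `start` (starting value for free parameters).
#' @param error_fractions named vector in `[0, 1)` over observed indicators
#'   (may be `NULL` for plain path models whose observed variances are paths).
#' @param phantom optional list describing a phantom composite latent:
#'   `variable` (its name), `parents` (the latents sending fixed paths into
#'   it), `error_fraction` f (its disturbance is constrained to
#'   `f/(1-f) *` the variance explained by the parents, i.e. error is a fixed
#'   share of total phantom variance), and `fixed` (if `TRUE`, the
#'   disturbance is frozen at its start-value implied magnitude instead of
#'   being recomputed each evaluation).
#' @return an object of class `sem_model`.
#' @seealso [build_whes_model()], [fit_sem()], [count_df()]
#' @export
sem_model <- function(variables, paths, error_fractions = NULL, phantom = NULL) {
  variables <- as.data.frame(variables, stringsAsFactors = FALSE)
  paths <- as.data.frame(paths, stringsAsFactors = FALSE)
  if (!all(c("name", "kind") %in% names(variables))) stop("variables needs columns name, kind")
  if (is.null(variables$role)) variables$role <- ""
  if (anyDuplicated(variables$name)) {
    stop("duplicated variable name: ", variables$name[duplicated(variables$name)][1])
  }
  if (!all(variables$kind %in% c("observed", "latent"))) {
    stop("variable kind must be 'observed' or 'latent'")
  }
  need <- c("source", "target", "kind", "status")
  if (!all(need %in% names(paths))) stop("paths needs columns ", paste(need, collapse = ", "))
  if (is.null(paths$value)) paths$value <- NA_real_
  if (is.null(paths$label)) paths$label <- NA_character_
  if (is.null(paths$start)) paths$start <- NA_real_
  vn <- variables$name
  bad <- setdiff(c(paths$source, paths$target), vn)
  if (length(bad) > 0) stop("path references unknown variable(s): ", paste(unique(bad), collapse = ", "))
  if (!all(paths$kind %in% c("directed", "covariance"))) stop("path kind must be 'directed' or 'covariance'")
  if (!all(paths$status %in% c("fixed", "free"))) stop("path status must be 'fixed' or 'free'")
  fx <- paths$status == "fixed"
  if (any(is.na(paths$value[fx]))) stop("fixed path without a value: ",
                                        paths$source[fx & is.na(paths$value)][1], " -> ",
                                        paths$target[fx & is.na(paths$value)][1])
  if (any(is.na(paths$label[!fx]) | paths$label[!fx] == "")) stop("free path without a label")
  dup <- duplicated(paths[, c("source", "target", "kind")]) |
    (paths$kind == "covariance" &
       duplicated(data.frame(a = pmin(paths$source, paths$target),
                             b = pmax(paths$source, paths$target), k = paths$kind)))
  if (any(dup)) stop("duplicated path: ", paths$source[dup][1], " -- ", paths$target[dup][1])
  if (!is.null(error_fractions)) {
    if (is.null(names(error_fractions))) stop("error_fractions must be named")
    ef <- error_fractions[setdiff(names(error_fractions), "phantom")]
    if (any(ef < 0 | ef >= 1)) stop("error fractions must lie in [0, 1)")
    unk <- setdiff(names(ef), vn[variables$kind == "observed"])
    if (length(unk) > 0) stop("error fraction for non-observed variable: ", paste(unk, collapse = ", "))
  }
  m <- structure(
    list(variables = variables, paths = paths,
         error_fractions = error_fractions, phantom = phantom),
    class = "sem_model")
  dir <- paths[paths$kind == "directed", , drop = FALSE]
  if (has_cycle(dir$source, dir$target, vn)) stop("directed paths contain a cycle; the model must be recursive")
  if (count_df(m) < 0) stop("negative degrees of freedom: model has more free parameters than observed moments")
  m
}

has_cycle <- function(src, tgt, nodes) {
  adj <- split(tgt, factor(src, levels = nodes))
  state <- stats::setNames(rep(0L, length(nodes)), nodes) # 0 new, 1 in stack, 2 done
  visit <- function(v) {
    if (state[[v]] == 1L) return(TRUE)
    if (state[[v]] == 2L) return(FALSE)
    state[[v]] <<- 1L
    for (w in adj[[v]]) if (visit(w)) return(TRUE)
    state[[v]] <<- 2L
    FALSE
  }
  for (v in nodes) if (state[[v]] == 0L && visit(v)) return(TRUE)
  FALSE
}

#' Ordered labels of the free parameters of a model
#' @param m a [sem_model].
#' @return character vector of unique labels in path order.
#' @export
free_parameters <- function(m) {
  unique(m$paths$label[m$paths$status == "free"])
}

#' Degrees of freedom of a covariance-structure model
#'
#' `p(p+1)/2 - q`, where `p` is the number of observed variables and `q` the
#' number of free parameters.  Fixed reliability-based error variances and
#' the constrained phantom disturbance do not count as free.
#'
#' @param m a [sem_model].
#' @return integer degrees of freedom.
#' @export
count_df <- function(m) {
  p <- sum(m$variables$kind == "observed")
  (p * (p + 1L)) %/% 2L - length(free_parameters(m))
}

#' @export
print.sem_model <- function(x, ...) {
  p <- sum(x$variables$kind == "observed")
  cat("sem_model:", nrow(x$variables), "variables (", p, "observed ),",
      nrow(x$paths), "paths,", length(free_parameters(x)), "free parameters, df =",
      count_df(x), "\n")
  if (!is.null(x$phantom)) {
    cat("phantom composite:", x$phantom$variable, "<-",
        paste(x$phantom$parents, collapse = " + "),
        sprintf("(disturbance = %.0f%% of total variance)\n", 100 * x$phantom$error_fraction))
  }
  invisible(x)
}

#' Error fractions of the final published lifetime-abuse / CVD-risk model
#'
#' One minus the assumed reliability of each indicator, after the published
#' respecification: self-report scales at 1 - Cronbach's alpha where
#' unadjusted (CTQ .06), adjusted values for ASA/ISA (.15), the five CES-D
#' waves (.30), BMI (.16), SBP/DBP (.25); smoking .05 (sensitivity/
#' specificity of self-report), waist circumference .05, age .01 (verified
#' against recorded birth dates), and .20 for the phantom composite itself
#' (no direct indicator of lifetime abuse exists).
#'
#' @return named numeric vector over the 14 indicators plus `"phantom"`.
#' @export
default_error_fractions <- function() {
  c(AGE = .01, CTQ = .06, ASA = .15, ISA = .15,
    CESD1 = .30, CESD2 = .30, CESD3 = .30, CESD4 = .30, CESD5 = .30,
    SMOKE = .05, WC = .05, BMI = .16, SBP = .25, DBP = .25, phantom = .20)
}

#' Variance of a three-source phantom composite
#'
#' The explained variance of a phantom latent receiving fixed unit paths
#' from three correlated sources:
#' `Var = Var1 + Var2 + Var3 + 2 Cov12 + 2 Cov13 + 2 Cov23`.
#'
#' @param exo_variances numeric vector of the 3 source variances (positive).
#' @param exo_covariances numeric vector of the 3 pairwise covariances
#'   (order 1-2, 1-3, 2-3).
#' @return the composite variance.
#' @export
phantom_explained_variance <- function(exo_variances, exo_covariances) {
  if (length(exo_variances) != 3 || length(exo_covariances) != 3) {
    stop("expected 3 variances and 3 covariances")
  }
  if (any(exo_variances <= 0)) stop("source variances must be positive")
  v <- sum(exo_variances) + 2 * sum(exo_covariances)
  if (v <= 0) stop("implied composite variance is not positive (inadmissible): ", v)
  v
}

whes_observed <- function() {
  c("AGE", "CTQ", "ASA", "ISA", paste0("CESD", 1:5), "SMOKE", "WC", "BMI", "SBP", "DBP")
}

#' Build the final lifetime-abuse / CVD-risk structural model
#'
#' Constructs the published model linking cumulative lifetime abuse to
#' cardiovascular disease risk in the Women's Health Effects Study cohort:
#'
#' * four single-indicator exogenous latents (child abuse / CTQ, partner
#'   abuse / ISA, adult sexual assault / ASA, age), loadings fixed at 1,
#'   error variances fixed from the error fractions; the three abuse latents
#'   freely covary (age does not covary with abuse);
#' * a phantom "lifetime abuse" composite receiving fixed unit paths from the
#'   three abuse latents, its disturbance constrained to 20% of its total
#'   variance;
#' * a latent growth curve over the five depressive-symptom waves: intercept
#'   loadings fixed at 1; slope loadings fixed at 0/1/2 for waves 1-3 and
#'   free for the waves in `free_slope_times`; intercept and slope
#'   disturbances freely covary;
#' * smoking (single indicator), body weight (BMI loading fixed 1, waist
#'   circumference loading free) and CVD risk (systolic loading fixed 1,
#'   diastolic loading free);
#' * 13 free structural paths: lifetime abuse to intercept, slope, smoking,
#'   body weight and CVD risk; intercept to body weight; slope to smoking,
#'   body weight and CVD risk; smoking to body weight and CVD risk; body
#'   weight to CVD risk; age to CVD risk.
#'
#' With the default arguments the model has 30 free parameters against
#' 105 observed moments, hence 75 degrees of freedom.
#'
#' @param error_fractions named vector as from [default_error_fractions()];
#'   must cover all 14 indicators (and may include `"phantom"`).
#' @param free_slope_times integer wave indices (2-5) whose slope loadings
#'   are freely estimated; default `c(4, 5)`.
#' @return a [sem_model].
#' @export
build_whes_model <- function(error_fractions = default_error_fractions(),
                             free_slope_times = c(4, 5)) {
  obs <- whes_observed()
  miss <- setdiff(obs, names(error_fractions))
  if (length(miss) > 0) stop("error fraction missing for indicator(s): ", paste(miss, collapse = ", "))
  if (any(error_fractions[obs] >= 1)) stop("error fractions must be < 1")
  stopifnot(all(free_slope_times %in% 2:5))

  lat <- data.frame(
    name = c("ChildAbuse", "PartnerAbuse", "ASAlat", "AgeLat", "LifetimeAbuse",
             "DepIntercept", "DepSlope", "Smoking", "BodyWeight", "CVDRisk"),
    kind = "latent",
    role = c("abuse-source", "abuse-source", "abuse-source", "exogenous", "phantom",
             "growth-intercept", "growth-slope", "behavior", "behavior", "outcome"))
  variables <- rbind(
    data.frame(name = obs, kind = "observed", role = "indicator"), lat)

  fixed <- function(s, t, k, v) data.frame(source = s, target = t, kind = k,
                                           status = "fixed", value = v,
                                           label = NA_character_, start = NA_real_)
  free <- function(s, t, k, lab, st = NA_real_) data.frame(source = s, target = t, kind = k,
                                                           status = "free", value = NA_real_,
                                                           label = lab, start = st)
  paths <- list(
    # measurement: single indicators
    fixed("ChildAbuse", "CTQ", "directed", 1),
    fixed("PartnerAbuse", "ISA", "directed", 1),
    fixed("ASAlat", "ASA", "directed", 1),
    fixed("AgeLat", "AGE", "directed", 1),
    fixed("Smoking", "SMOKE", "directed", 1),
    # two-indicator latents: scale set by the first indicator
    fixed("BodyWeight", "BMI", "directed", 1),
    free("BodyWeight", "WC", "directed", "lam_WC", 1),
    fixed("CVDRisk", "SBP", "directed", 1),
    free("CVDRisk", "DBP", "directed", "lam_DBP", 1),
    # growth curve
    fixed("DepIntercept", paste0("CESD", 1:5), "directed", 1))
  for (t in 1:5) {
    score <- t - 1
    paths[[length(paths) + 1]] <-
      if (t %in% free_slope_times) {
        free("DepSlope", paste0("CESD", t), "directed", paste0("lam_slope_t", t), score)
      } else {
        fixed("DepSlope", paste0("CESD", t), "directed", score)
      }
  }
  # phantom composite: fixed unit paths from the abuse latents
  abuse <- c("ChildAbuse", "PartnerAbuse", "ASAlat")
  paths[[length(paths) + 1]] <- fixed(abuse, "LifetimeAbuse", "directed", 1)
  # structural paths (13)
  st <- list(
    c("LifetimeAbuse", "DepIntercept"), c("LifetimeAbuse", "DepSlope"),
    c("LifetimeAbuse", "Smoking"), c("LifetimeAbuse", "BodyWeight"),
    c("LifetimeAbuse", "CVDRisk"),
    c("DepIntercept", "BodyWeight"),
    c("DepSlope", "Smoking"), c("DepSlope", "BodyWeight"), c("DepSlope", "CVDRisk"),
    c("Smoking", "BodyWeight"), c("Smoking", "CVDRisk"),
    c("BodyWeight", "CVDRisk"), c("AgeLat", "CVDRisk"))
  for (pp in st) {
    paths[[length(paths) + 1]] <-
      free(pp[1], pp[2], "directed", paste0("b_", pp[1], "_", pp[2]), 0.1)
  }
  # exogenous variances and covariances
  for (e in c(abuse, "AgeLat")) {
    paths[[length(paths) + 1]] <- free(e, e, "covariance", paste0("v_", e))
  }
  for (pp in utils::combn(abuse, 2, simplify = FALSE)) {
    paths[[length(paths) + 1]] <-
      free(pp[1], pp[2], "covariance", paste0("c_", pp[1], "_", pp[2]))
  }
  # endogenous disturbances (phantom's is constrained, not listed)
  for (d in c("DepIntercept", "DepSlope", "Smoking", "BodyWeight", "CVDRisk")) {
    paths[[length(paths) + 1]] <- free(d, d, "covariance", paste0("d_", d))
  }
  paths[[length(paths) + 1]] <- free("DepIntercept", "DepSlope", "covariance", "dc_IS")

  ph_frac <- if ("phantom" %in% names(error_fractions)) unname(error_fractions[["phantom"]]) else 0.20
  sem_model(variables, do.call(rbind, paths),
            error_fractions = error_fractions[obs],
            phantom = list(variable = "LifetimeAbuse", parents = abuse,
                           error_fraction = ph_frac, fixed = FALSE))
}

#' Write a model to a declarative text file
#'
#' One record per line, whitespace separated:
#' `variable <name> <kind> [role]`,
#' `path <source> <target> <directed|covariance> fixed <value>` or
#' `path <source> <target> <directed|covariance> free <label> [start]`,
#' `error <indicator> <fraction>`, and
#' `phantom <variable> <fraction> <parent,parent,...>`.
#' Lines starting with `#` are comments.
#'
#' @param m a [sem_model].
#' @param path output file path.
#' @export
write_model_spec <- function(m, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# phantomsem model specification", con)
  for (i in seq_len(nrow(m$variables))) {
    v <- m$variables[i, ]
    writeLines(paste("variable", v$name, v$kind, v$role), con)
  }
  for (i in seq_len(nrow(m$paths))) {
    p <- m$paths[i, ]
    rec <- if (p$status == "fixed") {
      paste("path", p$source, p$target, p$kind, "fixed", format(p$value, digits = 15))
    } else if (is.na(p$start)) {
      paste("path", p$source, p$target, p$kind, "free", p$label)
    } else {
      paste("path", p$source, p$target, p$kind, "free", p$label, format(p$start, digits = 15))
    }
    writeLines(rec, con)
  }
  for (nm in names(m$error_fractions)) {
    writeLines(paste("error", nm, format(m$error_fractions[[nm]], digits = 15)), con)
  }
  if (!is.null(m$phantom)) {
    writeLines(paste("phantom", m$phantom$variable,
                     format(m$phantom$error_fraction, digits = 15),
                     paste(m$phantom$parents, collapse = ",")), con)
  }
  invisible(m)
}

#' Read a model from the declarative text format
#' @param path file written by [write_model_spec()] (or by hand).
#' @return a [sem_model].
#' @export
read_model_spec <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  vars <- list(); paths <- list(); errs <- c(); phantom <- NULL
  for (ln in lines) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    switch(tok[1],
      variable = {
        vars[[length(vars) + 1]] <- data.frame(
          name = tok[2], kind = tok[3],
          role = if (length(tok) >= 4) paste(tok[-(1:3)], collapse = " ") else "")
      },
      path = {
        if (tok[5] == "fixed") {
          paths[[length(paths) + 1]] <- data.frame(
            source = tok[2], target = tok[3], kind = tok[4], status = "fixed",
            value = as.numeric(tok[6]), label = NA_character_, start = NA_real_)
        } else {
          paths[[length(paths) + 1]] <- data.frame(
            source = tok[2], target = tok[3], kind = tok[4], status = "free",
            value = NA_real_, label = tok[6],
            start = if (length(tok) >= 7) as.numeric(tok[7]) else NA_real_)
        }
      },
      error = { errs[tok[2]] <- as.numeric(tok[3]) },
      phantom = {
        phantom <- list(variable = tok[2], error_fraction = as.numeric(tok[3]),
                        parents = strsplit(tok[4], ",")[[1]], fixed = FALSE)
      },
      stop("unrecognized record type: ", tok[1]))
  }
  sem_model(do.call(rbind, vars), do.call(rbind, paths),
            error_fractions = if (length(errs)) errs else NULL, phantom = phantom)
}
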