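# Condition-effect estimation: linear mixed models with subject random
# intercepts (lme4/lmerTest), optionally with a continuous ERP-amplitude
# fixed effect and its interaction with condition (for linking ERP
# amplitudes to SSD/SSRT). Two fixed candidate models (main effects vs
# interaction) are compared by AIC and both AICs are reported; model
# selection is not optimised over.

#' Estimate condition effects with subject random intercepts
#'
#' Fits \code{response ~ condition + (1 | subject)} (plus an ERP amplitude
#' main effect or its interaction with condition when \code{erp} is given)
#' using lmerTest. The condition factor is releveled to \code{reference}
#' so fixed effects are differences from that condition. A singular fit
#' falls back to within-subject paired contrasts against the reference
#' (flagged in the result).
#'
#' @param data data.frame with at least the response, condition and subject
#'   columns.
#' @param response,condition,subject,erp column names; \code{erp} optional.
#' @param reference condition reference level (default: "none" if present,
#'   else the first level).
#' @param interaction include the erp x condition interaction (requires
#'   \code{erp}).
#' @return an [EffectEstimate-class]
#' @export
fitConditionEffect <- function(data, response = "value",
                               condition = "condition", subject = "subject",
                               erp = NULL, reference = NULL,
                               interaction = FALSE) {
  stopifnot(all(c(response, condition, subject) %in% names(data)))
  d <- data
  d[[condition]] <- factor(d[[condition]])
  if (is.null(reference))
    reference <- if ("none" %in% levels(d[[condition]]))
      "none" else levels(d[[condition]])[1]
  d[[condition]] <- stats::relevel(d[[condition]], ref = reference)
  d[[subject]] <- factor(d[[subject]])
  if (nlevels(d[[condition]]) < 2) stop("need at least 2 conditions")
  if (nlevels(d[[subject]]) < 3) stop("need at least 3 subjects")

  fixedMain <- if (is.null(erp)) condition else paste(erp, "+", condition)
  fml <- function(fixed) stats::as.formula(
    paste(response, "~", fixed, "+ (1 |", subject, ")"))
  aic <- c()
  # candidate models are compared by AIC under maximum likelihood; the
  # reported fit uses REML for unbiased variance (hence SE) estimates
  if (!is.null(erp)) {
    aic <- c(
      main = AIC(suppressMessages(lmerTest::lmer(fml(fixedMain), data = d,
                                                 REML = FALSE))),
      interaction = AIC(suppressMessages(lmerTest::lmer(
        fml(paste(erp, "*", condition)), data = d, REML = FALSE))))
    usedFixed <- if (interaction) paste(erp, "*", condition) else fixedMain
  } else {
    aic <- c(main = AIC(suppressMessages(lmerTest::lmer(fml(fixedMain),
                                                        data = d,
                                                        REML = FALSE))))
    usedFixed <- fixedMain
  }
  usedFml <- fml(usedFixed)
  fit <- suppressMessages(lmerTest::lmer(usedFml, data = d, REML = TRUE))

  singular <- lme4::isSingular(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  ranVar <- vc$vcov[vc$grp == subject][1]
  co <- as.data.frame(summary(fit)$coefficients)
  names(co) <- c("estimate", "se", "df", "t", "p")[seq_len(ncol(co))]
  co <- cbind(term = rownames(co), co)
  rownames(co) <- NULL

  fallback <- FALSE
  if (singular && is.null(erp)) {
    # degenerate random-intercept variance: report within-subject paired
    # contrasts against the reference instead
    fallback <- TRUE
    lev <- levels(d[[condition]])
    rows <- lapply(lev[-1], function(ll) {
      wide <- tapply(d[[response]],
                     list(d[[subject]], d[[condition]]), mean)
      dd <- wide[, ll] - wide[, lev[1]]
      dd <- dd[is.finite(dd)]
      tt <- if (length(dd) >= 2 && sd(dd) > 0) stats::t.test(dd) else NULL
      data.frame(term = paste0(condition, ll),
                 estimate = mean(dd),
                 se = sd(dd) / sqrt(length(dd)),
                 df = length(dd) - 1,
                 t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
                 p = if (is.null(tt)) NA_real_ else tt$p.value)
    })
    mu <- mean(tapply(d[[response]][d[[condition]] == lev[1]],
                      d[[subject]][d[[condition]] == lev[1]], mean),
               na.rm = TRUE)
    co <- rbind(data.frame(term = "(Intercept)", estimate = mu,
                           se = NA_real_, df = NA_real_, t = NA_real_,
                           p = NA_real_),
                do.call(rbind, rows))
  }

  new("EffectEstimate", coefficients = co, ranefVar = ranVar,
      formula = deparse(usedFml), aic = aic, singular = singular,
      fallback = fallback, fit = fit)
}
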