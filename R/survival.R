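#' TLS cell-signature score matrix
#'
#' Scores bulk expression samples for the seven TLS-associated
#' cell-cluster signatures (see [tlsSignatureNames()]) with single-sample
#' GSEA and z-standardises each signature across samples.
#'
#' @param expr gene x sample bulk expression matrix.
#' @param signatures [SignatureSet-class] (or named list) containing all
#'   seven TLS signatures; an error lists any that are missing.
#' @param alpha,rescale passed to [ssgseaScore()].
#' @return signature x sample matrix of z-scores (rows have mean 0,
#'   sd 1).
#' @export
tlsCsMatrix <- function(expr, signatures, alpha = 0.25, rescale = FALSE) {
  need <- tlsSignatureNames()
  have <- if (methods::is(signatures, "SignatureSet"))
    names(signatures) else names(signatures)
  miss <- setdiff(need, have)
  if (length(miss))
    stop("missing TLS signature(s): ", paste(miss, collapse = ", "))
  sigs <- if (methods::is(signatures, "SignatureSet"))
    signatures@signatures[need] else signatures[need]
  es <- ssgseaScore(expr, sigs, alpha = alpha, rescale = rescale)
  t(zScoreColumns(es))
}

#' Split samples into high/low TLS-CS modules
#'
#' Hierarchical clustering (Euclidean distance, Ward linkage) of the
#' samples on their signature z-scores, cut into two modules; the module
#' with the greater mean total score is labelled `high`.
#'
#' @param scores signature x sample matrix (e.g. from [tlsCsMatrix()]);
#'   at least 4 samples.
#' @return named factor (high/low) per sample.
#' @export
clusterTwoModules <- function(scores) {
  if (ncol(scores) < 4L) stop("at least 4 samples required")
  d <- dist(t(scores))
  if (all(d == 0)) stop("all samples identical; cannot form two modules")
  cl <- cutree(hclust(d, method = "ward.D2"), k = 2L)
  mu <- tapply(colSums(scores), cl, mean)
  high <- names(mu)[which.max(mu)]
  factor(setNames(ifelse(cl == as.integer(high), "high", "low"),
                  colnames(scores)),
         levels = c("low", "high"))
}

#' ROC-optimal score cutoff
#'
#' Scans all midpoints between sorted unique scores and returns the
#' threshold maximising Youden's J (sensitivity + specificity - 1) for
#' classifying the binary outcome as `score > threshold`; ties take the
#' smallest threshold. The closest-to-(0,1) criterion is available as an
#' alternative.
#'
#' @param score numeric vector.
#' @param outcome binary vector (0/1 or logical), both classes present.
#' @param criterion `"youden"` (default) or `"closest"`.
#' @return list with `threshold`, `J`, `sensitivity`, `specificity`.
#' @export
rocOptimalCutoff <- function(score, outcome, criterion = c("youden", "closest")) {
  criterion <- match.arg(criterion)
  y <- as.integer(outcome)
  stopifnot(length(score) == length(y), all(y %in% 0:1))
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  u <- sort(unique(score))
  if (length(u) < 2L) stop("scores are constant")
  thr <- (utils::head(u, -1L) + u[-1L]) / 2
  sens <- vapply(thr, function(t) mean(score[y == 1] > t), numeric(1L))
  spec <- vapply(thr, function(t) mean(score[y == 0] <= t), numeric(1L))
  J <- sens + spec - 1
  best <- if (criterion == "youden") {
    which(J == max(J))[1L]
  } else {
    dd <- (1 - sens)^2 + (1 - spec)^2
    which(dd == min(dd))[1L]
  }
  list(threshold = thr[best], J = J[best], sensitivity = sens[best],
       specificity = spec[best])
}

#' Kaplan-Meier survival estimate per group
#'
#' Product-limit estimator of the survival function for each group.
#'
#' @param surv data.frame with columns `time` (positive) and `event`
#'   (1 = event, 0 = censored).
#' @param groups group label per subject; a single group when `NULL`.
#' @return data.frame with columns `group`, `time`, `nRisk`, `nEvent`,
#'   `survival` (one row per event/censoring time; S(0) = 1 implicitly).
#' @export
kmEstimate <- function(surv, groups = NULL) {
  stopifnot(all(surv$time > 0), all(surv$event %in% 0:1))
  if (is.null(groups)) groups <- rep("all", nrow(surv))
  fit <- survival::survfit(
    survival::Surv(surv$time, surv$event) ~ g,
    data = data.frame(surv, g = groups))
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(unique(groups), length(sm$time))
    else sub("^g=", "", as.character(sm$strata))
  data.frame(group = grp, time = sm$time, nRisk = sm$n.risk,
             nEvent = sm$n.event, survival = sm$surv,
             stringsAsFactors = FALSE)
}

#' Cox proportional-hazards ratio
#'
#' Two-sided Cox test of a group indicator (optionally adjusted for
#' covariates), with Efron handling of tied event times. Monotone
#' likelihood (complete separation) is flagged and the coefficient capped
#' with a warning.
#'
#' @param surv data.frame with columns `time`, `event`.
#' @param group binary/two-level group indicator per subject (the hazard
#'   ratio is for the second level vs the first).
#' @param covariates optional data.frame of additional covariates.
#' @return list with `HR`, `ci` (95% Wald), `p` (two-sided), `beta`,
#'   `flagged` (monotone-likelihood indicator) and the fitted model as
#'   `fit`.
#' @export
coxHr <- function(surv, group, covariates = NULL) {
  g <- if (is.factor(group)) group else factor(group)
  if (nlevels(g) != 2L) stop("group must have exactly two levels")
  for (lv in levels(g)) {
    if (sum(surv$event[g == lv]) < 1L)
      stop("each group needs at least one event")
  }
  df <- data.frame(time = surv$time, event = surv$event, g = g)
  form <- event ~ g
  if (!is.null(covariates)) {
    df <- cbind(df, covariates)
    form <- stats::as.formula(
      paste("~ g +", paste(colnames(covariates), collapse = " + ")))
  } else form <- ~g
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(stats::as.formula(
      paste("survival::Surv(time, event)", paste(deparse(form), collapse = ""))),
      data = df, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be infinite", conditionMessage(w))) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  beta <- unname(stats::coef(fit)[1L])
  se <- sqrt(diag(fit$var))[1L]
  cap <- 20
  if (flagged || abs(beta) > cap) {
    flagged <- TRUE
    warning("monotone likelihood detected; coefficient capped at |beta| = ", cap)
    beta <- sign(beta) * min(abs(beta), cap)
  }
  p <- 2 * stats::pnorm(-abs(beta / se))
  list(HR = exp(beta), ci = exp(beta + c(-1, 1) * 1.96 * se), p = p,
       beta = beta, flagged = flagged, fit = fit)
}

#' Log-rank test between survival groups
#'
#' Standard observed-minus-expected chi-square statistic over event times,
#' with `g - 1` degrees of freedom.
#'
#' @param surv data.frame with columns `time`, `event`.
#' @param groups group label per subject (at least 2 groups).
#' @return list with `chisq`, `df`, `p`.
#' @export
logrankTest <- function(surv, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("at least 2 groups required")
  if (sum(surv$event) == 0L) stop("no events observed")
  fit <- survival::survdiff(
    survival::Surv(surv$time, surv$event) ~ g,
    data = data.frame(surv, g = groups))
  df <- nlevels(groups) - 1L
  list(chisq = fit$chisq, df = df,
       p = pchisq(fit$chisq, df = df, lower.tail = FALSE))
}
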