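# Clinical receptor-status handling: TNBC label construction with HER2 assay
# precedence, suspect-individual flagging, and confounder screening.

norm_status <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("missing", length(x))
  out[x %in% c("positive", "pos", "+")] <- "positive"
  out[x %in% c("negative", "neg", "-")] <- "negative"
  out[x %in% c("equivocal")] <- "equivocal"
  out[x %in% c("indeterminate")] <- "indeterminate"
  out
}

norm_level <- function(x) {
  x <- trimws(as.character(x))
  out <- rep("missing", length(x))
  out[x %in% c("0", "1+", "2+", "3+")] <- x[x %in% c("0", "1+", "2+", "3+")]
  out
}

# IHC level -> sign: 0 and 1+ are negative, 2+ indeterminate, 3+ positive
level_sign <- function(level) {
  c("0" = "negative", "1+" = "negative", "2+" = "indeterminate",
    "3+" = "positive", "missing" = "missing")[level]
}

determinate <- function(x) x %in% c("positive", "negative")

#' Build TNBC (triple-negative) labels with HER2 assay precedence
#'
#' Constructs the binary outcome: `y = 1` (TNBC) iff ER, PR and the resolved
#' HER2 call are all negative; `y = 0` if any of the three is positive.  The
#' HER2 call is taken from FISH when FISH is determinate (positive/negative)
#' -- FISH is the more accurate assay and replaces the IHC status for samples
#' measured by it -- otherwise from the IHC status when determinate,
#' otherwise it is missing.  Samples whose receptor calls cannot resolve the
#' label (no positive call and at least one missing) are excluded and listed
#' rather than erroring.
#'
#' @param clin data.frame with columns `sample_id`, `er_status`, `pr_status`,
#'   `her2_ihc_level` (`0`,`1+`,`2+`,`3+`), `her2_ihc_status`, `her2_fish`
#'   (status columns: positive/negative/equivocal/indeterminate/missing).
#' @return list with `labels` (data.frame: `sample_id`, `y`, `her2_source` in
#'   \{ihc_status, fish, none\}, `suspect`) and `excluded` (data.frame:
#'   `sample_id`, `reason`).
#' @export
build_tnbc_labels <- function(clin) {
  if (anyDuplicated(clin$sample_id)) stop("duplicate sample_id in clinical table")
  er <- norm_status(clin$er_status)
  pr <- norm_status(clin$pr_status)
  ihc <- norm_status(clin$her2_ihc_status)
  fish <- norm_status(clin$her2_fish)

  her2 <- rep("missing", nrow(clin))
  src <- rep("none", nrow(clin))
  use_ihc <- determinate(ihc)
  her2[use_ihc] <- ihc[use_ihc]
  src[use_ihc] <- "ihc_status"
  use_fish <- determinate(fish)
  her2[use_fish] <- fish[use_fish]
  src[use_fish] <- "fish"

  pos_any <- er == "positive" | pr == "positive" | her2 == "positive"
  neg_all <- er == "negative" & pr == "negative" & her2 == "negative"
  y <- ifelse(neg_all, 1L, ifelse(pos_any, 0L, NA_integer_))

  suspects <- flag_suspect_individuals(clin)
  labels <- data.frame(sample_id = clin$sample_id, y = y,
                       her2_source = src,
                       suspect = clin$sample_id %in% suspects$sample_id,
                       stringsAsFactors = FALSE)
  excluded <- labels[is.na(labels$y), "sample_id", drop = FALSE]
  if (nrow(excluded) > 0) {
    excluded$reason <- "unresolved receptor calls (no positive call, >=1 missing)"
  } else {
    excluded$reason <- character(0)
  }
  list(labels = labels[!is.na(labels$y), , drop = FALSE],
       excluded = excluded)
}

#' Flag samples with discordant HER2 assay calls ("suspect individuals")
#'
#' A sample is suspect when (a) its HER2 IHC level maps to the opposite sign
#' of its HER2 IHC status (level mapping: 0 and 1+ negative, 2+
#' indeterminate, 3+ positive), or (b) its determinate IHC status contradicts
#' a determinate FISH call.  Suspect labels may be wrong, making these
#' samples candidate outliers.
#'
#' @inheritParams build_tnbc_labels
#' @return data.frame with columns `sample_id`, `kind`
#'   (`level_vs_status` or `ihc_vs_fish`); zero rows when all concordant.
#' @export
flag_suspect_individuals <- function(clin) {
  lev <- level_sign(norm_level(clin$her2_ihc_level))
  ihc <- norm_status(clin$her2_ihc_status)
  fish <- norm_status(clin$her2_fish)
  opposite <- function(a, b) {
    determinate(a) & determinate(b) & a != b
  }
  lv <- opposite(lev, ihc)
  if_ <- opposite(ihc, fish)
  data.frame(
    sample_id = c(clin$sample_id[lv], clin$sample_id[if_]),
    kind = c(rep("level_vs_status", sum(lv)), rep("ihc_vs_fish", sum(if_))),
    stringsAsFactors = FALSE
  )
}

#' Screen clinical covariates for association with the outcome
#'
#' Univariate screening for potential confounders: continuous covariates are
#' tested by the Wald test of a univariate logistic regression, categorical
#' covariates by Fisher's exact test (two-sided, point-probability
#' summation) on the contingency table with the outcome.  Rows with a
#' missing covariate value are dropped per covariate; constant covariates get
#' p = 1 with a warning.
#'
#' @param covariates data.frame of covariates (numeric columns are treated as
#'   continuous, everything else as categorical).
#' @param y binary outcome aligned with the rows.
#' @param sig_level significance flag threshold (default 0.05).
#' @return data.frame with columns `covariate`, `test`, `p_value`,
#'   `significant`, and a `note` for separation or constancy.
#' @export
screen_confounders <- function(covariates, y, sig_level = 0.05) {
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(y)) stop("covariates and y must align")
  one <- function(name) {
    v <- covariates[[name]]
    keep <- !is.na(v) & v != ""
    vv <- v[keep]; yy <- y[keep]
    note <- ""
    if (length(unique(vv)) < 2) {
      warning("covariate '", name, "' is constant; p-value set to 1")
      return(data.frame(covariate = name, test = "none", p_value = 1,
                        note = "constant covariate"))
    }
    if (is.numeric(vv)) {
      g <- suppressWarnings(stats::glm(yy ~ vv, family = stats::binomial()))
      sm <- summary(g)$coefficients
      pval <- sm["vv", "Pr(>|z|)"]
      if (any(g$fitted.values < 1e-8 | g$fitted.values > 1 - 1e-8)) {
        note <- "possible separation"
      }
      data.frame(covariate = name, test = "logistic_wald", p_value = pval,
                 note = note)
    } else {
      tab <- table(factor(vv), factor(yy))
      pval <- stats::fisher.test(tab)$p.value
      data.frame(covariate = name, test = "fisher_exact", p_value = pval,
                 note = note)
    }
  }
  out <- do.call(rbind, lapply(names(covariates), one))
  out$significant <- out$p_value < sig_level
  rownames(out) <- NULL
  out[, c("covariate", "test", "p_value", "significant", "note")]
}
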