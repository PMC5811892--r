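#' Model comparison across MM basis-set variants
#'
#' Statistics mirroring the standard comparison of quantification methods:
#' per-subject averaging of quantified intensities, one-way
#' repeated-measures ANOVA across methods per metabolite, and
#' Bonferroni-corrected paired post-hoc tests against a reference method,
#' with percent differences on the subject-averaged means. No correction
#' is applied across metabolites (each metabolite is analyzed as its own
#' dependent variable).
#'
#' @name model_compare
NULL

#' Summarize one subject: per-metabolite mean over included voxels
#'
#' @param fit An `mrsi_fit`.
#' @param qa A [qa_filter()] result.
#' @param subject Subject identifier.
#' @param method Method label (one of the seven MM variants).
#' @param components Which amplitude columns to summarize (default: all).
#' @return Data frame with columns `subject`, `method`, `metabolite`,
#'   `mean_amplitude`.
#' @export
summarize_subject <- function(fit, qa, subject, method,
                              components = colnames(fit$amplitudes)) {
  stopifnot(inherits(fit, "mrsi_fit"))
  keep <- !qa$excluded & !fit$failed
  if (!any(keep)) stop("zero included voxels for subject ", subject)
  m <- colMeans(fit$amplitudes[keep, components, drop = FALSE], na.rm = TRUE)
  data.frame(subject = subject, method = method,
             metabolite = components, mean_amplitude = unname(m),
             stringsAsFactors = FALSE)
}

#' Compare quantification methods against a reference
#'
#' Input is a long table of subject-level summaries (rows: subject x
#' method x metabolite). Per metabolite: percent difference of each
#' method's grand mean from the reference, a one-way repeated-measures
#' ANOVA over methods (subject as the repeated factor, no sphericity
#' correction by default; Greenhouse-Geisser optionally), and paired
#' t-tests of each non-reference method against the reference with a
#' Bonferroni factor equal to the number of non-reference methods.
#'
#' @param summaries Data frame with columns `subject`, `method`,
#'   `metabolite`, `mean_amplitude`; the design must be complete.
#' @param reference Reference method label (default `"full_MM"`).
#' @param alpha Significance level (default 0.05).
#' @param gg_correction Apply the Greenhouse-Geisser epsilon to the ANOVA
#'   degrees of freedom (default `FALSE`).
#' @return A list of class `method_comparison`: `anova` (per-metabolite F,
#'   df, p), `posthoc` (per metabolite x method: percent difference,
#'   raw and Bonferroni-corrected p, significance at `alpha`).
#' @export
compare_methods <- function(summaries, reference = "full_MM", alpha = 0.05,
                            gg_correction = FALSE) {
  need <- c("subject", "method", "metabolite", "mean_amplitude")
  stopifnot(all(need %in% names(summaries)))
  subs <- unique(summaries$subject)
  meths <- unique(summaries$method)
  mets <- unique(summaries$metabolite)
  if (length(subs) < 3) stop("need >= 3 subjects")
  if (!reference %in% meths) stop("reference method absent: ", reference)
  full <- expand.grid(subject = subs, method = meths, metabolite = mets,
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$subject, d$method, d$metabolite, sep = "\r")
  missing <- setdiff(key(full), key(summaries))
  if (length(missing))
    stop("unbalanced design; missing cells: ",
         paste(utils::head(gsub("\r", "/", missing), 5), collapse = ", "),
         if (length(missing) > 5) " ..." else "")

  anova_rows <- NULL; post_rows <- NULL
  k <- length(meths)
  for (met in mets) {
    d <- summaries[summaries$metabolite == met, ]
    d$subject <- factor(d$subject); d$method <- factor(d$method)
    # wide matrix subjects x methods
    Y <- stats::xtabs(mean_amplitude ~ subject + method, data = d)
    aovfit <- stats::aov(mean_amplitude ~ method + Error(subject), data = d)
    tab <- summary(aovfit)[["Error: Within"]][[1]]
    Fv <- tab["method", "F value"]
    df1 <- tab["method", "Df"]; df2 <- tab["Residuals", "Df"]
    p <- tab["method", "Pr(>F)"]
    if (gg_correction) {
      eps <- gg_epsilon(Y)
      p <- stats::pf(Fv, eps * df1, eps * df2, lower.tail = FALSE)
    }
    anova_rows <- rbind(anova_rows, data.frame(
      metabolite = met, F = Fv, df1 = df1, df2 = df2, p = p,
      stringsAsFactors = FALSE))
    ref_mean <- mean(Y[, reference])
    others <- setdiff(colnames(Y), reference)
    for (mm in others) {
      dif <- Y[, mm] - Y[, reference]
      p_raw <- if (stats::sd(dif) < 1e-12 * max(1, mean(abs(Y[, reference])))) {
        1  # identical data under both methods: no evidence of a difference
      } else stats::t.test(Y[, mm], Y[, reference], paired = TRUE)$p.value
      p_adj <- min(1, p_raw * length(others))
      post_rows <- rbind(post_rows, data.frame(
        metabolite = met, method = mm,
        percent_difference = 100 * (mean(Y[, mm]) - ref_mean) / ref_mean,
        p_raw = p_raw, p_bonferroni = p_adj,
        significant = p_adj <= alpha, stringsAsFactors = FALSE))
    }
  }
  structure(list(anova = anova_rows, posthoc = post_rows,
                 reference = reference, alpha = alpha),
            class = "method_comparison")
}

# Greenhouse-Geisser epsilon from the subjects-x-methods matrix
gg_epsilon <- function(Y) {
  S <- stats::cov(Y)
  k <- ncol(S)
  dbar <- mean(diag(S)); sbar <- mean(S)
  num <- (k * (dbar - sbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * mean(rowMeans(S)^2) + k^2 * sbar^2)
  max(min(num / den, 1), 1 / (k - 1))
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("<method_comparison> reference:", x$reference, "\n\nANOVA per metabolite:\n")
  print(x$anova, digits = 4, row.names = FALSE)
  cat("\nPost-hoc vs reference (Bonferroni):\n")
  print(x$posthoc, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write / read a method-comparison report
#'
#' Tab-separated export mirroring a method x metabolite layout: percent
#' difference and corrected p per cell.
#'
#' @param cmp A `method_comparison`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_comparison_tsv <- function(cmp, path) {
  utils::write.table(cmp$posthoc, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
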