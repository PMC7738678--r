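# Repeat-composition vs morphometric-trait correlation, in the style of
# the within-clade mammalian analyses (QA ratio against a facial "shape"
# metric). Ordinary least squares only; the r-squared is reported unsigned
# with the slope's sign as a separate field (a printed negative r-squared
# in the literature is shorthand for a negative association, not a
# mathematical quantity). No phylogenetic correction is applied.

#' Correlate QA ratios with a morphometric trait
#'
#' Ordinary least squares of the trait on the QA ratio across the taxa
#' shared by both inputs. Taxa with undefined (`NA`) ratios are excluded
#' with a logged count. The result carries a `phylo_naive` flag: no PGLS
#' correction is applied, matching the analyses this reproduces.
#'
#' @param ratios Named numeric vector, taxon -> QA ratio.
#' @param traits Trait table as from [read_trait_table()] (columns
#'   `taxon`, `trait`, `value`).
#' @param trait_name Which trait to regress.
#' @return A `qa_regression`: `n`, `slope`, `intercept`, `r2` (squared
#'   Pearson correlation), `sign` (`"+"`/`"-"`, the slope's sign), `p`
#'   (two-sided for the slope), `trait`, `excluded` (count of dropped
#'   undefined ratios), `phylo_naive = TRUE`.
#' @export
correlate <- function(ratios, traits, trait_name) {
  stopifnot(is.numeric(ratios), !is.null(names(ratios)),
            is.data.frame(traits))
  tt <- traits[traits$trait == trait_name, , drop = FALSE]
  if (nrow(tt) == 0) stop("trait '", trait_name, "' not found in trait table")
  ok <- is.finite(ratios)
  excluded <- sum(!ok)
  if (excluded > 0) {
    message(excluded, " taxa excluded: undefined QA ratio")
  }
  r <- ratios[ok]
  common <- intersect(names(r), tt$taxon)
  if (length(common) < 3) {
    stop("need at least 3 taxa present in both inputs, got ", length(common))
  }
  x <- unname(r[common])
  y <- tt$value[match(common, tt$taxon)]
  if (stats::sd(x) == 0) stop("zero variance in variable 'ratio'")
  if (stats::sd(y) == 0) stop("zero variance in variable '", trait_name, "'")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  structure(list(n = length(common), slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = sm$r.squared,
                 sign = if (slope >= 0) "+" else "-",
                 p = sm$coefficients[2, 4],
                 trait = trait_name, excluded = excluded,
                 phylo_naive = TRUE),
            class = "qa_regression")
}

#' @export
print.qa_regression <- function(x, ...) {
  cat(sprintf("QA ratio vs %s: n = %d, r2 = %.3f (sign %s), p = %.3g\n",
              x$trait, x$n, x$r2, x$sign, x$p))
  cat(sprintf("  slope = %.4g, intercept = %.4g\n", x$slope, x$intercept))
  cat("  note: phylogenetically naive (no PGLS correction)\n")
  invisible(x)
}
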