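# Bench-assay calculators: m6A-IP-qPCR relative enrichment (2^-dCT,
# reference-gene and input normalized), LC-MS/MS standard-curve
# nucleoside quantification with the m6A/A ratio, and Sanger-bisulfite
# per-cytosine 5mC levels with region summaries.

#' m6A-IP-qPCR relative enrichment
#'
#' Technical-replicate CT values are averaged per group before
#' exponentiation. The immunoprecipitated signal is normalized against
#' the reference gene (ACTIN), then against the equally normalized
#' input:
#' `enrichment = 2^-(CT_IP,gene - CT_IP,ref) / 2^-(CT_in,gene - CT_in,ref)`.
#' Adding a constant to all four mean CTs leaves the result unchanged.
#'
#' @param ct_ip_gene,ct_ip_ref,ct_input_gene,ct_input_ref Numeric
#'   vectors of CT values (cycles) for the target gene and the
#'   reference gene in the IP and input fractions.
#' @return Dimensionless relative enrichment.
#' @export
qpcr_enrichment <- function(ct_ip_gene, ct_ip_ref, ct_input_gene,
                            ct_input_ref) {
  groups <- list(ct_ip_gene, ct_ip_ref, ct_input_gene, ct_input_ref)
  if (any(vapply(groups, function(x) length(x) == 0L || anyNA(x),
                 logical(1))))
    stop("all four CT groups must be present and free of missing values")
  if (any(unlist(groups) <= 0)) stop("CT values must be positive")
  m <- vapply(groups, mean, numeric(1))
  rel_ip <- 2^-(m[1L] - m[2L])
  rel_in <- 2^-(m[3L] - m[4L])
  rel_ip / rel_in
}

#' Relative mRNA level by 2^-dCT
#'
#' @param ct_gene,ct_ref CT vectors for the gene and the reference
#'   gene (averaged before exponentiation).
#' @return `2^-(mean CT_gene - mean CT_ref)`.
#' @export
qpcr_expression <- function(ct_gene, ct_ref) {
  if (!length(ct_gene) || !length(ct_ref) || anyNA(c(ct_gene, ct_ref)))
    stop("both CT groups must be present and free of missing values")
  2^-(mean(ct_gene) - mean(ct_ref))
}

#' Fit an LC-MS/MS standard curve
#'
#' Ordinary least squares of peak area on concentration (free
#' intercept).
#'
#' @param concentrations Strictly increasing concentration series
#'   (>= 3 points).
#' @param areas Matching peak areas.
#' @param nucleoside Label, e.g. `"A"` or `"m6A"`.
#' @return list of class `standard_curve` with `slope`, `intercept`,
#'   `r_squared`, `nucleoside`, and the input points.
#' @export
fit_standard_curve <- function(concentrations, areas, nucleoside = "") {
  if (length(concentrations) < 3L || length(areas) != length(concentrations))
    stop("standard curve needs >= 3 matched (concentration, area) points")
  if (any(diff(concentrations) <= 0))
    stop("concentrations must be strictly increasing")
  fit <- stats::lm(areas ~ concentrations)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope <= 0)
    stop("standard curve slope must be positive")
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((areas - mean(areas))^2)
  structure(list(nucleoside = nucleoside, slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 concentrations = concentrations, areas = areas),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard_curve %s: area = %.4g * conc + %.4g (R^2 = %.4f)\n",
              x$nucleoside, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Invert a standard curve
#'
#' @param curve A [fit_standard_curve()] result.
#' @param area Peak area(s).
#' @return Concentration(s): `(area - intercept) / slope`.
#' @export
quantify_area <- function(curve, area) {
  stopifnot(inherits(curve, "standard_curve"))
  (area - curve$intercept) / curve$slope
}

#' m6A/A ratio from peak areas
#'
#' Both nucleosides are quantified against their own standard curve;
#' the ratio is reported as a percentage.
#'
#' @param area_a,area_m6a Peak areas for A and m6A.
#' @param curve_a,curve_m6a Their standard curves.
#' @return `100 * conc(m6A) / conc(A)` (percent).
#' @export
m6a_ratio <- function(area_a, area_m6a, curve_a, curve_m6a) {
  conc_a <- quantify_area(curve_a, area_a)
  conc_m <- quantify_area(curve_m6a, area_m6a)
  if (any(conc_a <= 0)) stop("non-positive A concentration")
  100 * conc_m / conc_a
}

#' Per-cytosine 5mC levels from bisulfite Sanger clones
#'
#' For every cytosine of the reference, clones retaining C are counted
#' as methylated and clones converted to T as unmethylated; other
#' bases are tallied as mismatches and ignored. The sequence context
#' (CpG/CHG/CHH, H = A/C/T) is called from the reference; missing
#' downstream bases at the 3' end are treated as H.
#'
#' @param reference Reference sequence (character or `DNAString`).
#' @param clones Character vector or `DNAStringSet` of pre-aligned,
#'   gap-free clone sequences, each the same length as the reference.
#' @return data.frame of class `bisulfite_sites`: `position` (1-based),
#'   `context`, `n_c`, `n_t`, `n_other`, `level` (= n_C/(n_C+n_T), in
#'   [0, 1]). Sites with no C or T call are dropped with a warning.
#' @export
bisulfite_levels <- function(reference, clones) {
  ref <- toupper(as.character(reference))
  cl <- toupper(as.character(clones))
  L <- nchar(ref)
  if (any(nchar(cl) != L))
    stop("clone length differs from reference length")
  refv <- strsplit(ref, "")[[1L]]
  clm <- do.call(rbind, strsplit(cl, ""))
  cpos <- which(refv == "C")
  context <- vapply(cpos, function(i) {
    nxt1 <- if (i + 1L <= L) refv[i + 1L] else "H"
    nxt2 <- if (i + 2L <= L) refv[i + 2L] else "H"
    if (nxt1 == "G") "CpG" else if (nxt2 == "G") "CHG" else "CHH"
  }, character(1))
  n_c <- colSums(clm[, cpos, drop = FALSE] == "C")
  n_t <- colSums(clm[, cpos, drop = FALSE] == "T")
  n_other <- nrow(clm) - n_c - n_t
  out <- data.frame(position = cpos, context = context, n_c = n_c,
                    n_t = n_t, n_other = n_other,
                    level = n_c / (n_c + n_t), row.names = NULL)
  bad <- out$n_c + out$n_t == 0L
  if (any(bad)) {
    warning(sum(bad), " cytosine site(s) with no C/T call excluded")
    out <- out[!bad, , drop = FALSE]
  }
  class(out) <- c("bisulfite_sites", "data.frame")
  out
}

#' Summary statistics for a differentially methylated region
#'
#' @param sites [bisulfite_levels()] output.
#' @param interval Optional `c(start, end)` (1-based, inclusive)
#'   restricting to reference positions within the region.
#' @return list with `n`, `mean`, `median`, `q1`, `q3` of per-site 5mC
#'   levels.
#' @export
dmr_summary <- function(sites, interval = NULL) {
  lv <- if (is.null(interval)) sites$level
  else sites$level[sites$position >= interval[1L] &
                     sites$position <= interval[2L]]
  if (!length(lv)) stop("no cytosine sites in the requested interval")
  qs <- stats::quantile(lv, c(0.25, 0.5, 0.75), names = FALSE)
  list(n = length(lv), mean = mean(lv), median = qs[2L],
       q1 = qs[1L], q3 = qs[3L])
}
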