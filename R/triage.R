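# Gene-level aggregation of per-line test results: evidence categories,
# the two-part stringent filter, the multi-stress count and report tables.

#' Bundled ETE abiotic-stress screen summary
#'
#' Per-line FDR-adjusted p-values for the TE-derived loci of the original
#' abiotic-stress screen, as published in its summary tables: one table
#' for genes supported by at least two T-DNA insertion lines and one for
#' genes with a single line. `value` holds the printed phenotype summary
#' (percent survival/germination/damage, or average root length in px
#' for phosphate). Freezing entries carry the screening year; both years
#' count as one stress throughout the triage functions.
#'
#' @param which `"multi"`, `"single"` or `"both"` (default).
#' @return Data frame with columns `locus`, `family`, `locus_name`,
#'   `superfamily`, `category_printed`, `stress`, `line_id`, `value`,
#'   `p_adj`, `year`, `table`. `line_id` distinguishes the T-DNA lines
#'   within a locus and stress; single-line genes keep the same
#'   `line_id` across stresses.
#' @export
ete_screen_results <- function(which = c("both", "multi", "single")) {
  which <- match.arg(which)
  read_one <- function(file, tag) {
    df <- read.csv(system.file("extdata", file, package = "phenoplate"),
                   colClasses = c(year = "character"))
    df$table <- tag
    df$line_id <- if (tag == "single") paste0(df$locus, ".L1")
      else paste0(df$locus, ".", df$stress, ".L", df$line_rank)
    df
  }
  out <- switch(which,
    multi = read_one("ete_screen_multiline.csv", "multi"),
    single = read_one("ete_screen_singleline.csv", "single"),
    both = rbind(read_one("ete_screen_multiline.csv", "multi"),
                 read_one("ete_screen_singleline.csv", "single")))
  out[, c("locus", "family", "locus_name", "superfamily",
          "category_printed", "stress", "line_id", "value", "p_adj",
          "year", "table")]
}

#' Wild-type reference values of the bundled screen summary
#'
#' @return Data frame with `stress`, `value` (percent or px) and `year`
#'   (freezing only).
#' @export
ete_screen_wildtype <- function() {
  read.csv(system.file("extdata", "ete_screen_wildtype.csv",
                       package = "phenoplate"),
           colClasses = c(year = "character"))
}

# distinct significant lines per stress for one locus
sig_lines_by_stress <- function(rows, alpha = 0.05) {
  sig <- rows[rows$p_adj < alpha, , drop = FALSE]
  if (!nrow(sig)) return(integer(0))
  tapply(sig$line_id, sig$stress, function(x) length(unique(x)))
}

#' Two-part stringent filter for stress-specific genes
#'
#' A gene has a strong, stress-specific response iff there is a stress
#' assay in which (1) at least two distinct T-DNA lines are significant
#' (`p_adj < alpha`) and (2) the smallest adjusted p-value within that
#' same stress is below `strong`. Freezing years are pooled as one
#' stress.
#'
#' @param results data frame with columns `locus`, `line_id`, `stress`,
#'   `p_adj` (e.g. [ete_screen_results()] or [line_significance()]
#'   output joined to loci).
#' @param alpha per-line significance level (default 0.05).
#' @param strong strong-evidence level within the qualifying stress
#'   (default 0.01).
#' @return Data frame with one row per locus: `locus`, `pass`,
#'   `qualifying_stresses` (comma-separated, empty when failing).
#' @export
stringent_filter <- function(results, alpha = 0.05, strong = 0.01) {
  loci <- sort(unique(results$locus))
  if (!length(loci))
    return(data.frame(locus = character(0), pass = logical(0),
                      qualifying_stresses = character(0)))
  rows <- lapply(loci, function(lc) {
    r <- results[results$locus == lc, , drop = FALSE]
    nls <- sig_lines_by_stress(r, alpha)
    qual <- names(nls)[vapply(names(nls), function(st) {
      nls[[st]] >= 2 &&
        min(r$p_adj[r$stress == st & r$p_adj < alpha]) < strong
    }, logical(1))]
    data.frame(locus = lc, pass = length(qual) > 0,
               qualifying_stresses = paste(sort(qual), collapse = ","))
  })
  do.call(rbind, rows)
}

#' Count genes with strong evidence in more than one stress
#'
#' Counts the loci whose minimum adjusted p-value is below `strong` in
#' two or more stress conditions (freezing years pooled).
#'
#' @inheritParams stringent_filter
#' @param strong adjusted p-value threshold (default 0.01).
#' @return Integer count.
#' @export
multi_stress_count <- function(results, strong = 0.01) {
  if (!nrow(results)) return(0L)
  hits <- tapply(results$p_adj < strong, list(results$locus, results$stress),
                 any)
  sum(rowSums(hits, na.rm = TRUE) >= 2, na.rm = TRUE)
}

#' Assign an evidence category to each gene
#'
#' Genes with at least one significant line are placed in categories by a
#' decision tree over three questions: (1) are two or more distinct lines
#' significant in the *same* stress? then Category 6 (concordant
#' alleles); (2) otherwise, are two or more usable alleles each
#' significant somewhere? then Category 5; (3) otherwise, do the
#' significant results span more than one condition? then Category 3;
#' else Category 1. The intermediate multi-condition and multi-allele
#' states are reported as flags (`multi_condition`, `multi_allele`,
#' corresponding to Categories 2 and 4). Genes without a significant
#' line get `NA`.
#'
#' Allele metadata may override the tree per gene (`category_override`
#' in `alleles`), for cases where allele suitability known only from the
#' bench (e.g. an insertion in a position unlikely to disrupt the gene)
#' changes the call.
#'
#' @inheritParams stringent_filter
#' @param alleles optional data frame with `locus` and any of
#'   `n_alleles_available`, `category_override`.
#' @return Data frame with one row per locus: `locus`, `category`,
#'   `multi_condition`, `multi_allele`, `n_sig_lines`, `n_sig_stresses`.
#' @export
assign_category <- function(results, alleles = NULL, alpha = 0.05) {
  loci <- sort(unique(results$locus))
  if (!length(loci))
    return(data.frame(locus = character(0), category = integer(0),
                      multi_condition = logical(0), multi_allele = logical(0),
                      n_sig_lines = integer(0), n_sig_stresses = integer(0)))
  rows <- lapply(loci, function(lc) {
    r <- results[results$locus == lc, , drop = FALSE]
    sig <- r[r$p_adj < alpha, , drop = FALSE]
    n_lines <- length(unique(sig$line_id))
    n_stress <- length(unique(sig$stress))
    nls <- sig_lines_by_stress(r, alpha)
    cat <- if (!nrow(sig)) NA_integer_
      else if (any(nls >= 2)) 6L
      else if (n_lines >= 2) 5L
      else if (n_stress > 1) 3L
      else 1L
    data.frame(locus = lc, category = cat,
               multi_condition = n_stress > 1,
               multi_allele = n_lines >= 2,
               n_sig_lines = n_lines, n_sig_stresses = n_stress)
  })
  out <- do.call(rbind, rows)
  if (!is.null(alleles) && "category_override" %in% names(alleles)) {
    m <- match(out$locus, alleles$locus)
    ov <- alleles$category_override[m]
    out$category <- ifelse(!is.na(ov), ov, out$category)
  }
  out
}

#' Per-gene summary of a screen
#'
#' Joins the category tree, the stringent filter and basic counts into
#' one row per locus.
#'
#' @inheritParams assign_category
#' @param strong strong-evidence level for the stringent filter.
#' @return Data frame with one row per locus (sorted by locus).
#' @export
summarize_genes <- function(results, alleles = NULL, alpha = 0.05,
                            strong = 0.01) {
  cats <- assign_category(results, alleles, alpha)
  sf <- stringent_filter(results, alpha, strong)
  minp <- tapply(results$p_adj, results$locus, min)
  out <- merge(cats, sf, by = "locus")
  out$min_p_adj <- as.numeric(minp[out$locus])
  out[order(out$locus), ]
}

#' Report tables: stringent passers and single-line candidates
#'
#' Splits the per-line results into the two summary views used to report
#' a screen: genes passing the stringent filter (with all their
#' per-stress values and p-values), and genes with exactly one usable
#' line but at least one significant result (candidates awaiting more
#' alleles).
#'
#' @inheritParams summarize_genes
#' @return List with data frames `stringent` and `single_line`, both
#'   stably sorted by locus.
#' @export
build_report_tables <- function(results, alleles = NULL, alpha = 0.05,
                                strong = 0.01) {
  summ <- summarize_genes(results, alleles, alpha, strong)
  passers <- summ$locus[summ$pass]
  singles <- summ$locus[!summ$pass & summ$n_sig_lines == 1 &
                          vapply(summ$locus, function(lc) {
                            length(unique(results$line_id[
                              results$locus == lc])) == 1
                          }, logical(1))]
  ord <- function(df) df[order(df$locus, df$stress), , drop = FALSE]
  list(stringent = ord(results[results$locus %in% passers, , drop = FALSE]),
       single_line = ord(results[results$locus %in% singles, , drop = FALSE]))
}
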