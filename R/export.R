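# Simulated case-control cohorts and interoperability exports.
#
# These are smoke-test scale utilities: they materialize one simulated
# cohort's genotypes so downstream tools (bcftools, PLINK) can ingest the
# model's output, not an attempt at a general-purpose VCF library.

#' Simulate a case-control cohort of genotypes
#'
#' Draws individuals under the model (per-locus Hardy-Weinberg genotypes,
#' damage-rule phenotypes) and retains them until the requested numbers of
#' cases (left-handers) and controls are reached, so genotype frequencies in
#' each group follow the exact conditional distributions.
#'
#' @param model A [dc_model()].
#' @param n_cases,n_controls Individuals to retain per group.
#' @param seed Optional integer seed.
#' @return A tibble with columns `sample_id`, `status` (`"case"` /
#'   `"control"`) and one `locus*` column per locus holding chance-allele
#'   counts (0, 1, 2).
#' @examples
#' simulate_cohort(dc_model(c = 0.2), 5, 10, seed = 1)
#' @export
simulate_cohort <- function(model, n_cases, n_controls, seed = NULL) {
  check_model(model)
  n_cases <- check_count(n_cases, "n_cases", min = 0)
  n_controls <- check_count(n_controls, "n_controls", min = 0)
  prev <- population_left_rate(model)
  if (n_cases > 0 && prev <= 0) stop_degenerate("Cases are impossible: P(L) = 0.")
  if (n_controls > 0 && prev >= 1) stop_degenerate("Controls are impossible: P(L) = 1.")
  pen <- as.numeric(model$penetrance)
  if (n_cases == 0 && n_controls == 0) {
    out <- tibble::as_tibble(as.data.frame(sample_genotypes(model, 1)[0, , drop = FALSE]))
    return(dplyr::bind_cols(
      tibble::tibble(sample_id = character(), status = character()), out
    ))
  }
  with_seed(seed, {
    need_case <- n_cases
    need_ctrl <- n_controls
    kept <- list()
    status <- character()
    while (need_case > 0 || need_ctrl > 0) {
      batch <- max(100L, ceiling(2 * (need_case / max(prev, 1e-3) + need_ctrl)))
      g <- sample_genotypes(model, batch)
      left <- stats::runif(batch) < pen[apply(g, 1, max) + 1]
      take_case <- which(left)[seq_len(min(need_case, sum(left)))]
      take_ctrl <- which(!left)[seq_len(min(need_ctrl, sum(!left)))]
      kept[[length(kept) + 1]] <- g[c(take_case, take_ctrl), , drop = FALSE]
      status <- c(status, rep("case", length(take_case)),
                  rep("control", length(take_ctrl)))
      need_case <- need_case - length(take_case)
      need_ctrl <- need_ctrl - length(take_ctrl)
    }
    g <- do.call(rbind, kept)
    ord <- order(factor(status, levels = c("case", "control")))
    out <- tibble::as_tibble(as.data.frame(g[ord, , drop = FALSE]))
    dplyr::bind_cols(
      tibble::tibble(
        sample_id = sprintf("S%04d", seq_along(status)),
        status = status[ord]
      ),
      out
    )
  })
}

cohort_genotype_matrix <- function(cohort) {
  loci <- grep("^locus", names(cohort), value = TRUE)
  if (length(loci) == 0 || !all(c("sample_id", "status") %in% names(cohort))) {
    stop_invalid("`cohort` must come from simulate_cohort().")
  }
  as.matrix(cohort[loci])
}

#' Write a simulated cohort as VCF or PLINK PED/MAP
#'
#' `write_cohort_vcf()` writes one biallelic VCFv4.2 record per locus
#' (REF = the dextral allele `A`, ALT = the chance allele `C`, unphased
#' `GT`), with the case/control status recorded in the header. Sites are
#' placed at arbitrary evenly spaced positions on chromosome 1, since the
#' model's loci are abstract, unlinked markers. `write_cohort_plink()`
#' writes the matching text PED/MAP pair with affection status 2 for cases
#' and 1 for controls.
#'
#' @param cohort A tibble from [simulate_cohort()].
#' @param path Output `.vcf` path.
#' @return The output path(s), invisibly.
#' @examples
#' cohort <- simulate_cohort(dc_model(c = 0.2), 3, 5, seed = 1)
#' vcf <- tempfile(fileext = ".vcf")
#' write_cohort_vcf(cohort, vcf)
#' @export
write_cohort_vcf <- function(cohort, path) {
  g <- cohort_genotype_matrix(cohort)
  gt <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=dcmodel simulated cohort (synthetic genotypes)",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "##contig=<ID=1>",
    paste0("##dcmodel_status=", paste(cohort$status, collapse = ",")),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$sample_id), collapse = "\t")
  )
  rows <- vapply(seq_len(ncol(g)), function(i) {
    paste(c("1", format(i * 1000L), paste0("locus", i), "A", "C", ".",
            "PASS", ".", "GT", gt[g[, i] + 1]), collapse = "\t")
  }, character(1))
  readr::write_lines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_cohort_vcf
#' @param prefix Output prefix; `<prefix>.ped` and `<prefix>.map` are
#'   written.
#' @export
write_cohort_plink <- function(cohort, prefix) {
  g <- cohort_genotype_matrix(cohort)
  allele_pairs <- c("A A", "A C", "C C")
  ped <- vapply(seq_len(nrow(g)), function(r) {
    paste(c(cohort$sample_id[r], cohort$sample_id[r], "0", "0", "0",
            if (cohort$status[r] == "case") "2" else "1",
            allele_pairs[g[r, ] + 1]), collapse = " ")
  }, character(1))
  map <- sprintf("1 locus%d 0 %d", seq_len(ncol(g)), seq_len(ncol(g)) * 1000L)
  readr::write_lines(ped, paste0(prefix, ".ped"))
  readr::write_lines(map, paste0(prefix, ".map"))
  invisible(paste0(prefix, c(".ped", ".map")))
}
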