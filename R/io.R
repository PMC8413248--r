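.cohort_required <- c("participant_id", "age", "sex", "bmi", "smoking",
                      "alcohol", "activity", "ethnicity", "tdi",
                      "diabetes", "cvd", "crp", "dep_score", "anx_score")

#' Write a cohort table to CSV
#'
#' Comma-separated, header row, UTF-8, '.' decimal separator. A comment
#' line records the generating seed when one is supplied, so every output
#' file carries its provenance.
#'
#' @param cohort cohort data frame.
#' @param path output file.
#' @param seed optional integer recorded in the file header.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, seed = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  utils::write.csv(cohort, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Validates the schema and value ranges: CRP must be positive, PHQ-9
#' scores in 0-27, GAD-7 scores in 0-21, genotype dosages in `[0, 2]`.
#' Rows violating a range check are rejected and returned in attribute
#' `rejected` with machine-readable reasons; a missing required column is
#' an error naming the column. Lines starting with `#` (provenance
#' headers) are skipped, and CRLF files parse identically to LF files.
#'
#' @param path CSV file as produced by [write_cohort()].
#' @return validated cohort data frame; attribute `rejected` holds a data
#'   frame of row indices and reason codes.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(.cohort_required, names(d))
  if (length(miss))
    stop("cohort file missing required column(s): ",
         paste(miss, collapse = ", "))
  gcols <- grep("^g_", names(d), value = TRUE)
  reasons <- character(nrow(d))
  bad <- function(cond, code) {
    cond[is.na(cond)] <- TRUE
    reasons[cond & reasons == ""] <<- code
  }
  bad(d$crp <= 0, "crp_not_positive")
  bad(d$dep_score < 0 | d$dep_score > 27, "dep_score_out_of_range")
  bad(d$anx_score < 0 | d$anx_score > 21, "anx_score_out_of_range")
  for (g in gcols) bad(d[[g]] < 0 | d[[g]] > 2, "dosage_out_of_range")
  keep <- reasons == ""
  rejected <- data.frame(row = which(!keep), reason = reasons[!keep])
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Read a GWAS summary-statistics instrument table
#'
#' Tab-separated with header `snp effect_allele other_allele eaf beta se
#' n` (the de-facto summary-statistics layout). Rows with non-positive
#' standard errors or malformed alleles are rejected with reasons;
#' duplicated variant ids are an error.
#'
#' @param path TSV file.
#' @return validated instrument data frame; rejected rows in attribute
#'   `rejected`.
#' @export
read_instruments <- function(path) {
  if (!file.exists(path)) stop("instrument file not found: ", path)
  d <- utils::read.delim(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("snp", "effect_allele", "other_allele", "eaf", "beta", "se")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("instrument file missing required column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(d$snp))
    stop("duplicated variant id(s): ",
         paste(unique(d$snp[duplicated(d$snp)]), collapse = ", "))
  reasons <- character(nrow(d))
  ok_allele <- function(a) a %in% c("A", "C", "G", "T")
  bad <- function(cond, code) {
    cond[is.na(cond)] <- TRUE
    reasons[cond & reasons == ""] <<- code
  }
  bad(!ok_allele(toupper(d$effect_allele)) |
        !ok_allele(toupper(d$other_allele)), "invalid_allele")
  bad(toupper(d$effect_allele) == toupper(d$other_allele),
      "identical_alleles")
  bad(d$se <= 0, "non_positive_se")
  bad(!is.na(d$eaf) & (d$eaf <= 0 | d$eaf >= 1), "eaf_out_of_range")
  keep <- reasons == ""
  rejected <- data.frame(row = which(!keep), reason = reasons[!keep])
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Write an instrument table
#' @param instruments instrument data frame.
#' @param path output TSV file.
#' @param seed optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_instruments <- function(instruments, path, seed = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  utils::write.table(instruments, con, row.names = FALSE, sep = "\t",
                     quote = FALSE)
  invisible(path)
}

#' Serialise / read a simulation truth record
#' @param truth truth record list from [generate_cohort()].
#' @param path JSON file.
#' @return `path` (write) or the truth list (read).
#' @export
write_truth <- function(truth, path) {
  # named vectors become named JSON objects, not bare arrays
  as_obj <- function(x) {
    if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else if (is.list(x)) lapply(x, as_obj)
    else x
  }
  jsonlite::write_json(as_obj(truth), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Export cohort genotypes as a minimal VCF 4.2 file
#'
#' GT fields are derived from rounded dosages; positions are synthetic
#' placeholders (one locus per SNP column, chromosome 1 for the CRP
#' region, chromosome 2 for the IL6R region).
#'
#' @param cohort cohort data frame with `g_` dosage columns.
#' @param path output `.vcf` file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(cohort, path) {
  gcols <- grep("^g_", names(cohort), value = TRUE)
  if (!length(gcols)) stop("cohort has no genotype columns")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=inflamr",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT",
                       paste0("S", cohort$participant_id)),
                     collapse = "\t")), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  for (i in seq_along(gcols)) {
    g <- pmin(pmax(round(cohort[[gcols[i]]]), 0), 2)
    chrom <- if (grepl("^g_CRP", gcols[i])) "1" else "2"
    writeLines(paste(c(chrom, 1000L + i, gcols[i], "G", "A", ".",
                       "PASS", ".", "GT", gt_codes[g + 1]),
                     collapse = "\t"), con)
  }
  invisible(path)
}
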