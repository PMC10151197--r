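#' GWAS summary-statistics datasets
#'
#' A `summary_dataset` holds per-variant association estimates for one trait:
#' one row per variant with the effect allele, the other allele, the
#' effect-allele frequency, the effect estimate (`beta`, in SD units of the
#' trait for continuous traits and log odds ratio for binary traits), its
#' standard error, the association p-value and sample sizes.
#'
#' @param records data.frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pval`, `n` and, for binary traits,
#'   `n_case` and `n_control`. Missing values are `NA`.
#' @param trait_id short trait label, e.g. `"EA"`.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param unit free-text unit of `beta`, e.g. `"SD of years of schooling"`.
#' @param validate if `TRUE` (default), rows violating hard invariants are
#'   removed and reported in the `"rejected"` attribute; duplicated variant
#'   ids are an error.
#'
#' @return An object of class `summary_dataset`: the validated `records`
#'   data.frame with attributes `trait_id`, `trait_type`, `unit` and
#'   `rejected` (a data.frame of `variant_id`, `reason` for dropped rows).
#' @export
summary_dataset <- function(records, trait_id, trait_type = c("continuous", "binary"),
                            unit = "", validate = TRUE) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(records))
  needed <- c("variant_id", "effect_allele", "other_allele", "eaf", "beta",
              "se", "pval", "n")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("n_case", "n_control")) {
    if (!col %in% names(records)) records[[col]] <- NA_real_
  }
  records <- records[, c(needed, "n_case", "n_control")]
  records$variant_id <- as.character(records$variant_id)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n", "n_case", "n_control")) {
    records[[col]] <- as.numeric(records[[col]])
  }

  rejected <- data.frame(variant_id = character(), reason = character())
  if (validate) {
    dup <- unique(records$variant_id[duplicated(records$variant_id)])
    if (length(dup) > 0) {
      stop("duplicate variant_id: ", paste(dup, collapse = ", "))
    }
    bad <- list(
      "invalid alleles" =
        !(records$effect_allele %in% NUCLEOTIDES) |
        !(records$other_allele %in% NUCLEOTIDES) |
        records$effect_allele == records$other_allele,
      "nonpositive se" = !is.finite(records$se) | records$se <= 0,
      "eaf out of range" = !is.na(records$eaf) &
        (records$eaf < 0 | records$eaf > 1),
      "invalid beta" = !is.finite(records$beta),
      "invalid pval" = !is.finite(records$pval) |
        records$pval <= 0 | records$pval > 1,
      "case-control mismatch" = trait_type == "binary" &
        !is.na(records$n_case) & !is.na(records$n_control) & !is.na(records$n) &
        abs(records$n_case + records$n_control - records$n) > 0.5
    )
    reason <- rep(NA_character_, nrow(records))
    for (lab in names(bad)) {
      hit <- bad[[lab]] & is.na(reason)
      reason[hit] <- lab
    }
    drop <- !is.na(reason)
    if (any(drop)) {
      rejected <- data.frame(variant_id = records$variant_id[drop],
                             reason = reason[drop])
      records <- records[!drop, , drop = FALSE]
    }
    # p-values in published tables are rounded; agreement with the Wald p to
    # within a factor of 10 is a soft check only.
    p_wald <- z_pval(records$beta, records$se)
    inconsistent <- is.finite(p_wald) & p_wald > 1e-300 &
      (records$pval / p_wald > 10 | p_wald / records$pval > 10)
    if (any(inconsistent)) {
      warning(sum(inconsistent), " record(s) with p-value inconsistent with ",
              "beta/se beyond a factor of 10 (kept)")
    }
  }
  rownames(records) <- NULL
  structure(records,
            class = c("summary_dataset", "data.frame"),
            trait_id = trait_id, trait_type = trait_type, unit = unit,
            rejected = rejected)
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat(sprintf("<summary_dataset> trait '%s' (%s), %d variants\n",
              attr(x, "trait_id"), attr(x, "trait_type"), nrow(x)))
  rej <- attr(x, "rejected")
  if (NROW(rej) > 0) cat(sprintf("  %d row(s) rejected at validation\n", nrow(rej)))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

trait_id <- function(ds) attr(ds, "trait_id")
trait_type <- function(ds) attr(ds, "trait_type")

#' Read GWAS summary statistics from the package's TSV dialect
#'
#' Tab-delimited with a header naming the columns `variant_id`,
#' `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`,
#' `n_case`, `n_control`; `"."` marks a missing value. Rows that violate hard
#' invariants (non-positive standard error, malformed alleles, out-of-range
#' frequencies or p-values) are rejected with a per-row report rather than
#' aborting the read.
#'
#' @param path file path.
#' @param trait_id,trait_type,unit trait descriptor, as [summary_dataset()].
#' @return A [summary_dataset()]; rejected rows are in `attr(, "rejected")`.
#' @export
read_sumstats <- function(path, trait_id, trait_type = c("continuous", "binary"),
                          unit = "") {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t", na.strings = ".",
                           colClasses = "character", quote = "",
                           comment.char = "", check.names = TRUE)
  summary_dataset(raw, trait_id = trait_id, trait_type = trait_type, unit = unit)
}

#' Write a summary dataset in the package's TSV dialect
#'
#' Inverse of [read_sumstats()]: `read_sumstats(write_sumstats(ds, p), ...)`
#' reproduces `ds` field for field. Missing values are written as `"."`.
#'
#' @param ds a [summary_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ds, path) {
  stopifnot(inherits(ds, "summary_dataset"))
  out <- data.frame(
    variant_id = ds$variant_id,
    effect_allele = ds$effect_allele,
    other_allele = ds$other_allele,
    eaf = num_chr(ds$eaf),
    beta = num_chr(ds$beta),
    se = num_chr(ds$se),
    pval = num_chr(ds$pval),
    n = num_chr(ds$n),
    n_case = num_chr(ds$n_case),
    n_control = num_chr(ds$n_control)
  )
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write sumstats to '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}
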