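#' Pairwise LD reference
#'
#' Sparse lookup of pairwise r-squared between variants plus 1-based physical
#' positions, supporting greedy clumping and proxy search. Symmetry is
#' enforced (pairs are stored once, on a canonical ordering), `r2(a, a)` is 1
#' and an absent pair means r2 = 0.
#'
#' @param pairs data.frame with columns `variant_id_a`, `variant_id_b`, `r2`.
#' @param positions data.frame with columns `variant_id`, `chrom`, `pos`
#'   (1-based base-pair coordinates).
#' @param window_bp physical distance bound within which pairs are stored.
#' @return An object of class `ld_reference`.
#' @export
ld_reference <- function(pairs, positions, window_bp = 1e7) {
  stopifnot(is.data.frame(pairs), is.data.frame(positions))
  if (!all(c("variant_id_a", "variant_id_b", "r2") %in% names(pairs))) {
    stop("pairs must have columns variant_id_a, variant_id_b, r2")
  }
  if (!all(c("variant_id", "chrom", "pos") %in% names(positions))) {
    stop("positions must have columns variant_id, chrom, pos")
  }
  pairs$r2 <- as.numeric(pairs$r2)
  if (any(!is.finite(pairs$r2) | pairs$r2 < 0 | pairs$r2 > 1)) {
    stop("r2 outside [0, 1]")
  }
  a <- as.character(pairs$variant_id_a)
  b <- as.character(pairs$variant_id_b)
  self <- a == b
  a <- a[!self]; b <- b[!self]; r2 <- pairs$r2[!self]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- tapply(r2, key, max)
    key <- names(agg); r2 <- as.numeric(agg)
    parts <- strsplit(key, "\r", fixed = TRUE)
    lo <- vapply(parts, `[`, "", 1L); hi <- vapply(parts, `[`, "", 2L)
  }
  lut <- r2
  names(lut) <- key
  positions$variant_id <- as.character(positions$variant_id)
  if (anyDuplicated(positions$variant_id)) stop("duplicate variant_id in positions")
  pos <- data.frame(chrom = as.character(positions$chrom),
                    pos = as.numeric(positions$pos),
                    row.names = positions$variant_id)
  structure(list(lut = lut,
                 pairs = data.frame(variant_id_a = lo, variant_id_b = hi, r2 = r2),
                 positions = pos, window_bp = window_bp),
            class = "ld_reference")
}

#' @export
print.ld_reference <- function(x, ...) {
  cat(sprintf("<ld_reference> %d stored pairs, %d positioned variants, window %g bp\n",
              nrow(x$pairs), nrow(x$positions), x$window_bp))
  invisible(x)
}

#' Look up pairwise r-squared
#'
#' Vectorized over `b`. Returns 1 on the diagonal and 0 for unseen pairs.
#'
#' @param ld an [ld_reference()].
#' @param a single variant id.
#' @param b character vector of variant ids.
#' @return numeric vector of r2 values, same length as `b`.
#' @export
ld_r2 <- function(ld, a, b) {
  stopifnot(inherits(ld, "ld_reference"), length(a) == 1L)
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  out <- unname(ld$lut[key])
  out[is.na(out)] <- 0
  out[b == a] <- 1
  out
}

# All stored partners of `id` with their r2, as a data.frame.
ld_partners <- function(ld, id) {
  hit_a <- ld$pairs$variant_id_a == id
  hit_b <- ld$pairs$variant_id_b == id
  data.frame(
    partner = c(ld$pairs$variant_id_b[hit_a], ld$pairs$variant_id_a[hit_b]),
    r2 = c(ld$pairs$r2[hit_a], ld$pairs$r2[hit_b])
  )
}

# TRUE where `others` lie within window_bp of `id` on the same chromosome.
# Variants without positions are treated as unlinked, with a warning.
ld_in_window <- function(ld, id, others, window_bp = ld$window_bp) {
  pos <- ld$positions
  known <- c(id, others) %in% rownames(pos)
  if (!all(known)) {
    warning("variant(s) missing from LD positions treated as unlinked: ",
            paste(utils::head(setdiff(c(id, others), rownames(pos)), 5L),
                  collapse = ", "))
  }
  if (!(id %in% rownames(pos))) return(rep(FALSE, length(others)))
  same <- !is.na(pos[others, "chrom"]) & pos[others, "chrom"] == pos[id, "chrom"]
  dist_ok <- abs(pos[others, "pos"] - pos[id, "pos"]) <= window_bp
  same & !is.na(dist_ok) & dist_ok
}

#' Read an LD reference from TSV files
#'
#' @param pairs_path TSV with columns `variant_id_a`, `variant_id_b`, `r2`.
#' @param positions_path TSV with columns `variant_id`, `chrom`, `pos`.
#' @param window_bp physical window bound, bp.
#' @return An [ld_reference()].
#' @export
read_ld <- function(pairs_path, positions_path, window_bp = 1e7) {
  pairs <- utils::read.table(pairs_path, header = TRUE, sep = "\t",
                             colClasses = c("character", "character", "numeric"),
                             quote = "", comment.char = "")
  positions <- utils::read.table(positions_path, header = TRUE, sep = "\t",
                                 colClasses = c("character", "character", "numeric"),
                                 quote = "", comment.char = "")
  ld_reference(pairs, positions, window_bp = window_bp)
}

#' Write an LD reference to TSV files
#'
#' @param ld an [ld_reference()].
#' @param pairs_path,positions_path output paths.
#' @return `pairs_path`, invisibly.
#' @export
write_ld <- function(ld, pairs_path, positions_path) {
  stopifnot(inherits(ld, "ld_reference"))
  out <- ld$pairs
  out$r2 <- num_chr(out$r2)
  utils::write.table(out, pairs_path, sep = "\t", quote = FALSE, row.names = FALSE)
  pos <- data.frame(variant_id = rownames(ld$positions),
                    chrom = ld$positions$chrom,
                    pos = num_chr(ld$positions$pos))
  utils::write.table(pos, positions_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(pairs_path)
}
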