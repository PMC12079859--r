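#' Construct an LD reference
#'
#' A window-limited, symmetric pairwise r-squared lookup over a set of
#' variants. Pairs not stored (or farther apart than `window_bp`) report
#' r2 = 0; the diagonal reports 1.
#'
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`.
#' @param pairs data.frame with columns `id1`, `id2`, `r2` (each unordered
#'   pair stored once suffices; symmetry is handled at lookup).
#' @param window_bp pairs separated by more than this many base pairs
#'   report r2 = 0 regardless of the stored value.
#' @return object of class `ld_reference`.
#' @export
ld_reference <- function(variants, pairs = NULL, window_bp = Inf) {
  variants <- as.data.frame(variants)[c("variant_id", "chrom", "pos")]
  variants$variant_id <- as.character(variants$variant_id)
  variants$pos <- as.integer(variants$pos)
  if (anyDuplicated(variants$variant_id) > 0) stop("duplicate variant ids in LD reference")
  tab <- new.env(parent = emptyenv(), size = max(2L * NROW(pairs), 16L))
  partners <- new.env(parent = emptyenv())
  if (!is.null(pairs) && nrow(pairs) > 0) {
    id1 <- as.character(pairs$id1); id2 <- as.character(pairs$id2)
    r2 <- as.numeric(pairs$r2)
    if (any(r2 < 0 | r2 > 1)) stop("r2 values must lie in [0, 1]")
    keep <- id1 != id2
    id1 <- id1[keep]; id2 <- id2[keep]; r2 <- r2[keep]
    key <- ifelse(id1 < id2, paste0(id1, "\r", id2), paste0(id2, "\r", id1))
    for (i in seq_along(key)) assign(key[i], r2[i], envir = tab)
    for (id in unique(c(id1, id2))) {
      other <- c(id2[id1 == id], id1[id2 == id])
      rr <- c(r2[id1 == id], r2[id2 == id])
      keep2 <- !duplicated(other)
      assign(id, data.frame(variant_id = other[keep2], r2 = rr[keep2],
                            stringsAsFactors = FALSE), envir = partners)
    }
  }
  structure(list(variants = variants, tab = tab, partners = partners,
                 window_bp = window_bp),
            class = "ld_reference")
}

ld_pos <- function(ld, ids) {
  idx <- match(ids, ld$variants$variant_id)
  if (anyNA(idx)) stop("unknown variant(s) in LD reference: ",
                       paste(head(ids[is.na(idx)], 5), collapse = ", "))
  ld$variants[idx, , drop = FALSE]
}

#' Pairwise r-squared lookup
#'
#' Vectorized over equal-length id vectors. Identical ids give 1; unknown
#' or unstored pairs, and pairs farther apart than the reference window,
#' give 0.
#'
#' @param ld an [ld_reference()].
#' @param ids1,ids2 character vectors of variant ids.
#' @return numeric vector of r2 values.
#' @export
ld_r2 <- function(ld, ids1, ids2) {
  ids1 <- as.character(ids1); ids2 <- as.character(ids2)
  if (length(ids1) == 1) ids1 <- rep(ids1, length(ids2))
  if (length(ids2) == 1) ids2 <- rep(ids2, length(ids1))
  out <- numeric(length(ids1))
  same <- ids1 == ids2
  out[same] <- 1
  if (any(!same)) {
    key <- ifelse(ids1 < ids2, paste0(ids1, "\r", ids2), paste0(ids2, "\r", ids1))
    for (i in which(!same)) {
      out[i] <- if (exists(key[i], envir = ld$tab, inherits = FALSE))
        get(key[i], envir = ld$tab) else 0
    }
    if (is.finite(ld$window_bp)) {
      v1 <- ld_pos(ld, ids1[!same]); v2 <- ld_pos(ld, ids2[!same])
      far <- v1$chrom != v2$chrom | abs(v1$pos - v2$pos) > ld$window_bp
      out[!same][far] <- 0
    }
  }
  out
}

#' List the stored LD partners of a variant
#'
#' Returns the variants with a stored r2 against `id`, annotated with
#' chromosome and position, window-filtered. Variants with no partners
#' yield a zero-row frame.
#'
#' @param ld an [ld_reference()].
#' @param id single variant id (must exist in the reference).
#' @return data.frame with columns `variant_id`, `r2`, `chrom`, `pos`.
#' @export
ld_partners <- function(ld, id) {
  ld_pos(ld, id)  # existence check
  if (!exists(id, envir = ld$partners, inherits = FALSE)) {
    return(data.frame(variant_id = character(0), r2 = numeric(0),
                      chrom = character(0), pos = integer(0)))
  }
  p <- get(id, envir = ld$partners)
  known <- p$variant_id %in% ld$variants$variant_id
  p <- p[known, , drop = FALSE]
  v <- ld_pos(ld, p$variant_id)
  p$chrom <- v$chrom; p$pos <- v$pos
  if (is.finite(ld$window_bp)) {
    me <- ld_pos(ld, id)
    p <- p[p$chrom == me$chrom & abs(p$pos - me$pos) <= ld$window_bp, , drop = FALSE]
  }
  rownames(p) <- NULL
  p
}

#' Read an LD reference from delimited text
#'
#' Accepts either three-column long format (id1, id2, r2; with header) or
#' a dense square matrix whose header row and first column carry variant
#' ids. Variant positions come from `variants`.
#'
#' @param path LD file path.
#' @param variants data.frame with `variant_id`, `chrom`, `pos` covering
#'   all ids in the file.
#' @param window_bp lookup window passed to [ld_reference()].
#' @return an `ld_reference`.
#' @export
read_ld <- function(path, variants, window_bp = Inf) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (ncol(dt) == 3 && all(c("id1", "id2", "r2") %in% names(dt))) {
    return(ld_reference(variants, dt, window_bp = window_bp))
  }
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  if (nrow(m) != ncol(m)) stop("dense LD matrix must be square")
  idx <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
  pairs <- data.frame(id1 = ids[idx[, 1]], id2 = ids[idx[, 2]],
                      r2 = m[idx])
  ld_reference(variants, pairs, window_bp = window_bp)
}

#' Write an LD reference in long format
#'
#' @param ld an [ld_reference()].
#' @param path output path (columns id1, id2, r2).
#' @export
write_ld <- function(ld, path) {
  keys <- ls(envir = ld$tab)
  if (length(keys) == 0) {
    out <- data.frame(id1 = character(0), id2 = character(0), r2 = numeric(0))
  } else {
    sp <- strsplit(keys, "\r", fixed = TRUE)
    out <- data.frame(id1 = vapply(sp, `[`, "", 1),
                      id2 = vapply(sp, `[`, "", 2),
                      r2 = vapply(keys, function(k) get(k, envir = ld$tab), 1))
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
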