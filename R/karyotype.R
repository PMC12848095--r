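#' Number of autosomes in a karyotype vector
#'
#' Karyotypes are represented as ordered integer copy-number vectors over the
#' 22 human autosomes (chr1..chr22); sex chromosomes are not tracked.
#' @export
N_AUTOSOMES <- 22L

#' Parse a karyotype string
#'
#' Karyotypes are written as dot-separated integer copy numbers, one per
#' autosome, e.g. \code{"2.2.2....2"} for the diploid state. This is the
#' format used in longitudinal count tables.
#'
#' @param text character scalar, dot-separated copy numbers.
#' @return Integer vector of length 22 (copy number per autosome).
#' @seealso [formatKaryotype()], [karyoMatrix()]
#' @examples
#' parseKaryotype(formatKaryotype(rep(2L, 22)))
#' @export
parseKaryotype <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tok <- strsplit(text, ".", fixed = TRUE)[[1L]]
  if (length(tok) != N_AUTOSOMES)
    stop("karyotype '", text, "' has ", length(tok), " tokens; expected ",
         N_AUTOSOMES, call. = FALSE)
  k <- suppressWarnings(as.integer(tok))
  num <- suppressWarnings(as.numeric(tok))
  bad <- which(is.na(k) | num != k | k < 0L)
  if (length(bad))
    stop("karyotype token '", tok[bad[1L]], "' (position ", bad[1L],
         ") is not a non-negative integer", call. = FALSE)
  k
}

#' Format a karyotype vector as a string
#'
#' @param k integer vector of length 22, or a matrix with 22 columns (one
#'   karyotype per row).
#' @return Character scalar (or vector for matrix input).
#' @export
formatKaryotype <- function(k) {
  if (is.matrix(k)) {
    stopifnot(ncol(k) == N_AUTOSOMES)
    return(apply(k, 1L, paste, collapse = "."))
  }
  stopifnot(length(k) == N_AUTOSOMES)
  paste(k, collapse = ".")
}

#' Convert karyotype strings to an integer matrix
#'
#' @param x character vector of karyotype strings.
#' @return Integer matrix, one row per karyotype, 22 columns, rownames set to
#'   the input strings.
#' @export
karyoMatrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == N_AUTOSOMES)
    if (is.null(rownames(x))) rownames(x) <- formatKaryotype(x)
    storage.mode(x) <- "integer"
    return(x)
  }
  m <- t(vapply(x, parseKaryotype, integer(N_AUTOSOMES)))
  dimnames(m) <- list(x, NULL)
  m
}

#' Manhattan distance between karyotypes
#'
#' The number of single-chromosome copy-number steps separating two
#' karyotypes; one missegregation changes one chromosome by +/-1, so this is
#' the minimal missegregation count between states.
#'
#' @param k1,k2 karyotype vectors (length 22), strings, or matrices with one
#'   karyotype per row (in which case distances are computed row-wise against
#'   `k2`, a single karyotype).
#' @return Non-negative integer (or vector).
#' @export
manhattanDist <- function(k1, k2) {
  if (is.character(k1)) k1 <- karyoMatrix(k1)
  if (is.character(k2)) k2 <- if (length(k2) == 1L) parseKaryotype(k2) else karyoMatrix(k2)
  if (is.matrix(k1)) {
    stopifnot(!is.matrix(k2), length(k2) == N_AUTOSOMES)
    return(as.integer(rowSums(abs(sweep(k1, 2L, k2)))))
  }
  if (length(k1) != length(k2))
    stop("karyotype length mismatch: ", length(k1), " vs ", length(k2))
  as.integer(sum(abs(k1 - k2)))
}

#' Enumerate one-missegregation-step neighbors
#'
#' All karyotypes differing from `k` by +/-1 on exactly one chromosome, in
#' fixed order (loss chr1, gain chr1, loss chr2, gain chr2, ...). A diploid
#' karyotype has 44 such neighbors; with `allowZero = FALSE` moves into
#' zero-copy (nonviable) states are dropped.
#'
#' @param k karyotype vector or string.
#' @param allowZero keep neighbors containing a zero copy number?
#' @return Integer matrix of neighbors (rows named by karyotype string), with
#'   attributes `chrom` (chromosome index) and `direction` (-1 loss, +1 gain).
#' @export
oneStepNeighbors <- function(k, allowZero = TRUE) {
  if (is.character(k)) k <- parseKaryotype(k)
  stopifnot(length(k) == N_AUTOSOMES)
  idx <- rep(seq_len(N_AUTOSOMES), each = 2L)
  dir <- rep(c(-1L, 1L), N_AUTOSOMES)
  nb <- matrix(rep(k, each = 2L * N_AUTOSOMES), nrow = 2L * N_AUTOSOMES)
  nb[cbind(seq_len(2L * N_AUTOSOMES), idx)] <-
    k[idx] + dir
  keep <- if (allowZero) nb[cbind(seq_along(idx), idx)] >= 0L else
    nb[cbind(seq_along(idx), idx)] >= 1L
  nb <- nb[keep, , drop = FALSE]
  rownames(nb) <- formatKaryotype(nb)
  attr(nb, "chrom") <- idx[keep]
  attr(nb, "direction") <- dir[keep]
  nb
}

#' Charted region of karyotype space around a frequent-clone set
#'
#' All viable karyotypes (every copy number >= 1) whose minimal Manhattan
#' distance to the frequent set is at most `radius`. With the default
#' `radius = 2` this is the region within two missegregations of the observed
#' frequent clones, the region over which fitness is interpolated.
#'
#' @param frequent character vector of karyotype strings (non-empty).
#' @param radius non-negative integer.
#' @return Character vector of karyotype strings (includes `frequent` itself,
#'   minus any nonviable members).
#' @export
chartedRegion <- function(frequent, radius = 2L) {
  if (length(frequent) == 0L) stop("frequent set is empty")
  stopifnot(radius >= 0L)
  km <- karyoMatrix(unique(frequent))
  viable <- rowSums(km == 0L) == 0L
  region <- rownames(km)[viable]
  frontier <- region
  r <- 0L
  while (r < radius && length(frontier)) {
    nxt <- unlist(lapply(frontier, function(s) {
      rownames(oneStepNeighbors(parseKaryotype(s), allowZero = FALSE))
    }), use.names = FALSE)
    frontier <- setdiff(unique(nxt), region)
    region <- c(region, frontier)
    r <- r + 1L
  }
  region
}

#' Size of the bounded karyotype state space, in exact integer arithmetic
#'
#' Number of karyotypes with copy numbers 1..`maxCopy` on each of `nChrom`
#' chromosomes, i.e. `maxCopy^nChrom`. Because this overflows double
#' precision already at 22 chromosomes and 8 copies (8^22 > 10^19), the
#' result is computed by schoolbook big-integer multiplication and returned
#' as a decimal string.
#'
#' @param nChrom,maxCopy positive integers.
#' @return Character scalar: the exact decimal representation.
#' @examples
#' stateSpaceSize(2, 3)  # "9"
#' @export
stateSpaceSize <- function(nChrom, maxCopy) {
  stopifnot(nChrom >= 1L, maxCopy >= 1L)
  # digits little-endian in base 1e4
  base <- 10000L
  mulSmall <- function(digs, x) {
    carry <- 0
    out <- numeric(0)
    for (d in digs) {
      v <- d * x + carry
      out <- c(out, v %% base)
      carry <- v %/% base
    }
    while (carry > 0) {
      out <- c(out, carry %% base)
      carry <- carry %/% base
    }
    out
  }
  digs <- 1
  for (i in seq_len(nChrom)) digs <- mulSmall(digs, maxCopy)
  n <- length(digs)
  parts <- sprintf("%04d", rev(digs))
  parts[1L] <- sub("^0+", "", parts[1L])
  paste(parts, collapse = "")
}

#' Compare two non-negative decimal integer strings
#' @return -1, 0 or 1 as a < b, a == b, a > b.
#' @keywords internal
#' @export
compareBigInt <- function(a, b) {
  a <- sub("^0+(?=.)", "", a, perl = TRUE)
  b <- sub("^0+(?=.)", "", b, perl = TRUE)
  if (nchar(a) != nchar(b)) return(sign(nchar(a) - nchar(b)))
  if (a == b) 0L else if (a > b) 1L else -1L
}

#' Derive per-cell karyotypes from binned copy-number calls
#'
#' Collapses a cells x bins integer copy-number matrix into 22-element
#' karyotype vectors by taking, for each cell and autosome, the modal integer
#' copy number across the bins assigned to that autosome. Ties are broken
#' toward the smaller copy number (deterministic, and conservative with
#' respect to whole-genome-doubling classification).
#'
#' @param cn integer matrix, cells in rows, genomic bins in columns.
#' @param binChrom autosome label per bin: integer (1..22) or "chrN" strings.
#' @return Integer matrix, cells x 22, rownames preserved from `cn`.
#' @export
modalKaryotypeFromBins <- function(cn, binChrom) {
  stopifnot(is.matrix(cn), ncol(cn) == length(binChrom))
  if (any(cn < 0) || any(cn != round(cn)))
    stop("copy-number entries must be non-negative integers")
  chrom <- as.integer(sub("^chr", "", as.character(binChrom)))
  if (any(is.na(chrom)))
    stop("unparseable autosome labels: ",
         paste(unique(binChrom[is.na(chrom)]), collapse = ", "))
  missing <- setdiff(seq_len(N_AUTOSOMES), chrom)
  if (length(missing))
    stop("no bins for autosome(s): ", paste(missing, collapse = ", "))
  out <- matrix(0L, nrow(cn), N_AUTOSOMES, dimnames = list(rownames(cn), NULL))
  for (c in seq_len(N_AUTOSOMES)) {
    sub <- cn[, chrom == c, drop = FALSE]
    out[, c] <- apply(sub, 1L, function(v) {
      tb <- table(v)
      vals <- as.integer(names(tb))
      min(vals[tb == max(tb)])  # tie -> smaller copy number
    })
  }
  out
}
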