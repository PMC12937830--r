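#' Read a PLINK bed/bim/fam genotype triplet
#'
#' Parses the SNP-major binary .bed layout directly: after the three magic
#' bytes (0x6c 0x1b 0x01), each marker is stored in ceil(n/4) bytes, two bits
#' per individual from the low bits up, with codes 00 = homozygous A1,
#' 10 = heterozygous, 11 = homozygous A2, 01 = missing. Genotypes are
#' returned as counts of the A1 allele (by PLINK convention the minor
#' allele), so 00 maps to 2, 10 to 1, 11 to 0.
#'
#' @param prefix Path prefix; \code{prefix.bed/.bim/.fam} must all exist.
#' @return An object of class \code{"genotype_matrix"}: list with
#'   \code{matrix} (n x m integer counts, NA for missing; row names
#'   individual ids, column names marker ids) and \code{markers} (data frame
#'   \code{chr}, \code{id}, \code{pos}, \code{a1}, \code{a2}).
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  missing <- !file.exists(paths)
  if (any(missing)) stop("missing PLINK file(s): ",
                         paste(paths[missing], collapse = ", "))
  fam <- utils::read.table(paths[3], stringsAsFactors = FALSE)
  bim <- utils::read.table(paths[2], stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  if (any(bim[[4]] < 0)) stop("negative base-pair position in .bim")
  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("corrupt .bed magic bytes in ", paths[1])
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files are supported")
  bpm <- ceiling(n / 4)                       # bytes per marker
  if (length(raw) - 3L != bpm * m)
    stop(".bed size inconsistent with .bim/.fam dimensions")
  bits <- matrix(as.integer(rawToBits(raw[-(1:3)])), nrow = 8L * bpm)
  lo <- bits[seq(1L, 2L * n, by = 2L), , drop = FALSE]
  hi <- bits[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  code <- lo + 2L * hi                        # n x m of 2-bit codes
  counts <- matrix(NA_integer_, n, m)
  counts[code == 0L] <- 2L
  counts[code == 2L] <- 1L
  counts[code == 3L] <- 0L
  ids <- as.character(fam[[2]])
  marker_ids <- as.character(bim[[2]])
  dimnames(counts) <- list(ids, marker_ids)
  markers <- data.frame(chr = as.character(bim[[1]]), id = marker_ids,
                        pos = as.integer(bim[[4]]),
                        a1 = as.character(bim[[5]]), a2 = as.character(bim[[6]]),
                        stringsAsFactors = FALSE)
  genotype_matrix(counts, markers)
}

#' Construct a genotype matrix object
#'
#' @param matrix n x m matrix of A1 allele counts in \{0, 1, 2, NA\}.
#' @param markers Data frame with columns \code{chr}, \code{id}, \code{pos}
#'   (and optionally \code{a1}, \code{a2}); one row per matrix column.
#' @return A \code{"genotype_matrix"} object.
#' @export
genotype_matrix <- function(matrix, markers) {
  if (ncol(matrix) != nrow(markers))
    stop("markers table and genotype columns disagree")
  if (is.null(markers$a1)) markers$a1 <- "A"
  if (is.null(markers$a2)) markers$a2 <- "B"
  if (!is.null(markers$id)) colnames(matrix) <- markers$id
  structure(list(matrix = matrix, markers = markers),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix: %d individuals x %d markers, %d chromosome(s)>\n",
              nrow(x$matrix), ncol(x$matrix), length(unique(x$markers$chr))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$matrix)

#' Write a genotype matrix as a PLINK bed/bim/fam triplet
#'
#' Inverse of \code{\link{read_plink}} (counts of A1 encoded back to the
#' 2-bit codes; NA written as the missing code).
#'
#' @param g A \code{genotype_matrix}.
#' @param prefix Output path prefix.
#' @return \code{prefix}, invisibly.
#' @export
write_plink <- function(g, prefix) {
  G <- g$matrix
  n <- nrow(G); m <- ncol(G)
  ids <- rownames(G); if (is.null(ids)) ids <- paste0("ind", seq_len(n))
  fam <- data.frame(ids, ids, 0L, 0L, 0L, -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  bim <- data.frame(g$markers$chr, g$markers$id, 0L, g$markers$pos,
                    g$markers$a1, g$markers$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  code <- matrix(1L, n, m)                    # default missing (01)
  code[!is.na(G) & G == 2L] <- 0L
  code[!is.na(G) & G == 1L] <- 2L
  code[!is.na(G) & G == 0L] <- 3L
  bpm <- ceiling(n / 4)
  pad <- 4L * bpm - n
  if (pad > 0) code <- rbind(code, matrix(0L, pad, m))
  lo <- code %% 2L; hi <- code %/% 2L
  bits <- matrix(0L, 8L * bpm, m)
  bits[seq(1L, by = 2L, length.out = 4L * bpm), ] <- lo
  bits[seq(2L, by = 2L, length.out = 4L * bpm), ] <- hi
  body <- packBits(as.integer(bits), "raw")
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(body, con)
  invisible(prefix)
}
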