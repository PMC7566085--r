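#' @include accessors.R
NULL

#' Read a binary alteration matrix from TSV
#'
#' Expects genes as rows and samples as columns: a header row of sample
#' identifiers and a first column of gene identifiers.  Entries must be 0 or
#' 1; anything else (including missing values) is a format error naming the
#' offending gene and sample — alterations are calls, not scores, and are
#' never imputed.
#'
#' @param path path to a tab-separated file.
#' @return an \linkS4class{AlterationMatrix}.
#' @seealso \code{\link{writeAlterations}}
#' @export
readAlterations <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           row.names = NULL, quote = "", comment.char = "")
  if (ncol(tab) < 2L)
    stop("alteration file needs a gene column plus at least one sample")
  gn <- tab[[1L]]
  if (anyDuplicated(gn))
    stop("duplicate gene identifier(s): ",
         paste(unique(gn[duplicated(gn)]), collapse = ", "))
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  bad <- which(!(vals %in% c("0", "1")))
  if (length(bad) > 0) {
    rc <- arrayInd(bad[1L], dim(vals))
    stop(sprintf(
      "non-binary entry '%s' at gene '%s', sample '%s'",
      vals[rc[1], rc[2]], gn[rc[1]], colnames(vals)[rc[2]]))
  }
  m <- matrix(as.integer(vals), nrow = nrow(vals),
              dimnames = list(gn, colnames(vals)))
  AlterationMatrix(m)
}

#' Write an alteration matrix as TSV
#'
#' Inverse of \code{\link{readAlterations}}: genes as rows, samples as
#' columns, header of sample identifiers, first column \code{gene}.
#'
#' @param x an \linkS4class{AlterationMatrix}.
#' @param path output file path.
#' @export
writeAlterations <- function(x, path) {
  stopifnot(is(x, "AlterationMatrix"))
  df <- data.frame(gene = genes(x), x@calls, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample phenotype from TSV
#'
#' Two tab-separated columns, \code{sample} and \code{value}, with a header
#' row.  Samples with a missing value are dropped with a message (count
#' reported); no imputation.
#'
#' @param path path to the file.
#' @return a \linkS4class{PhenotypeProfile} (not yet normalized).
#' @export
readPhenotype <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, quote = "",
                           comment.char = "",
                           colClasses = c("character", "numeric"))
  if (ncol(tab) < 2L)
    stop("phenotype file needs columns sample<TAB>value")
  w <- tab[[2L]]
  names(w) <- tab[[1L]]
  miss <- is.na(w)
  if (any(miss)) {
    message(sum(miss), " sample(s) dropped for missing phenotype values")
    w <- w[!miss]
  }
  if (anyDuplicated(names(w)))
    stop("duplicate sample identifier(s) in phenotype file")
  PhenotypeProfile(w, normalized = FALSE)
}

#' Write a phenotype profile as TSV
#' @param x a \linkS4class{PhenotypeProfile}.
#' @param path output file path.
#' @export
writePhenotype <- function(x, path) {
  stopifnot(is(x, "PhenotypeProfile"))
  df <- data.frame(sample = samples(x), value = unname(x@weights))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene interaction network from a weighted edge list
#'
#' STRING-style three-column TSV \code{gene1<TAB>gene2<TAB>score} with a
#' header row; scores in [0, 1].  Edges below \code{minEdgeScore} are dropped
#' at load (their endpoints are kept as isolated nodes only if another edge
#' retains them).  Self-loops are dropped; duplicate pairs keep the maximum
#' score.
#'
#' @param path path to the edge list.
#' @param minEdgeScore confidence threshold in [0, 1]; default 0 keeps all.
#' @return a \linkS4class{GeneNetwork}.
#' @export
readNetwork <- function(path, minEdgeScore = 0) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, quote = "",
                           comment.char = "",
                           colClasses = c("character", "character",
                                          "numeric"))
  if (ncol(tab) < 3L)
    stop("network file needs columns gene1<TAB>gene2<TAB>score")
  names(tab)[1:3] <- c("gene1", "gene2", "score")
  if (anyNA(tab$score) || any(tab$score < 0 | tab$score > 1))
    stop("edge scores must lie in [0, 1]")
  tab <- tab[tab$score >= minEdgeScore & tab$gene1 != tab$gene2, ,
             drop = FALSE]
  GeneNetwork(tab)
}

#' Write a gene network as a weighted edge list
#' @param x a \linkS4class{GeneNetwork}.
#' @param path output file path.
#' @export
writeNetwork <- function(x, path) {
  stopifnot(is(x, "GeneNetwork"))
  g <- x@graph
  el <- igraph::as_edgelist(g)
  ## canonical order so load -> write -> load is a fixed point
  swap <- el[, 1] > el[, 2]
  el[swap, ] <- el[swap, c(2, 1), drop = FALSE]
  df <- data.frame(gene1 = el[, 1], gene2 = el[, 2],
                   score = if (igraph::ecount(g)) igraph::E(g)$score
                           else numeric())
  df <- df[order(df$gene1, df$gene2), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Z-score a phenotype profile
#'
#' Centers to mean 0 and scales to population standard deviation 1
#' (denominator \eqn{n}).  Centering makes the expected weight of a randomly
#' covered sample zero, so module objectives measure association rather than
#' coverage volume.  With \code{negate = TRUE} the raw values are sign-flipped
#' first, accommodating IC50-style inputs where smaller means more sensitive;
#' the package convention is that larger weight = more sensitive.
#'
#' Idempotent: re-normalizing an already z-scored profile leaves it unchanged
#' (up to 1e-9).
#'
#' @param x a \linkS4class{PhenotypeProfile}.
#' @param negate flip the sign of the raw values before scaling.
#' @return a normalized \linkS4class{PhenotypeProfile}.
#' @export
normalizePhenotype <- function(x, negate = FALSE) {
  stopifnot(is(x, "PhenotypeProfile"))
  w <- x@weights
  if (length(w) < 2L)
    stop("need at least 2 samples to normalize")
  if (negate) w <- -w
  s <- sqrt(sum((w - mean(w))^2) / length(w))
  if (s < 1e-12)
    stop("degenerate phenotype: zero variance")
  PhenotypeProfile((w - mean(w)) / s, normalized = TRUE)
}

#' Align an alteration matrix and a phenotype profile
#'
#' Restricts both objects to the intersection of their sample sets, in the
#' phenotype's order, reporting how many samples each side loses.
#'
#' @param A an \linkS4class{AlterationMatrix}.
#' @param w a \linkS4class{PhenotypeProfile}.
#' @return list with elements \code{alterations} and \code{phenotype}.
#' @export
alignSamples <- function(A, w) {
  stopifnot(is(A, "AlterationMatrix"), is(w, "PhenotypeProfile"))
  common <- intersect(samples(w), samples(A))
  if (length(common) == 0L)
    stop("no samples shared between alterations and phenotype")
  dropA <- length(samples(A)) - length(common)
  dropW <- length(samples(w)) - length(common)
  if (dropA + dropW > 0)
    message(sprintf(
      "sample alignment dropped %d alteration and %d phenotype sample(s)",
      dropA, dropW))
  list(alterations = AlterationMatrix(A@calls[, common, drop = FALSE]),
       phenotype = PhenotypeProfile(w@weights[common],
                                    normalized = w@normalized))
}

#' Filter genes by alteration frequency and network membership
#'
#' Retains genes whose fraction of altered samples lies in
#' \code{[minFreq, maxFreq]}.  With \code{requireInNetwork}, genes absent
#' from the network are also dropped (connectivity constraints are undefined
#' for them); each such drop is reported.  Retained rows are never modified.
#'
#' @param A an \linkS4class{AlterationMatrix}.
#' @param network a \linkS4class{GeneNetwork}, required when
#'   \code{requireInNetwork}.
#' @param minFreq,maxFreq alteration-frequency bounds in [0, 1].
#' @param requireInNetwork drop genes not present in \code{network}.
#' @return a filtered \linkS4class{AlterationMatrix}; an empty result is
#'   returned with a warning, not an error.
#' @export
filterGenes <- function(A, network = NULL, minFreq = 0.01, maxFreq = 1,
                        requireInNetwork = !is.null(network)) {
  stopifnot(is(A, "AlterationMatrix"),
            minFreq >= 0, maxFreq <= 1, minFreq <= maxFreq)
  freq <- rowMeans(A@calls)
  keep <- freq >= minFreq & freq <= maxFreq
  if (requireInNetwork) {
    if (is.null(network))
      stop("requireInNetwork needs a network")
    inNet <- genes(A) %in% genes(network)
    dropped <- genes(A)[keep & !inNet]
    if (length(dropped))
      message(length(dropped), " gene(s) dropped (absent from network): ",
              paste(utils::head(dropped, 10), collapse = ", "),
              if (length(dropped) > 10) ", ..." else "")
    keep <- keep & inNet
  }
  if (!any(keep))
    warning("no genes survive the filter")
  AlterationMatrix(A@calls[keep, , drop = FALSE])
}

#' Read drug target gene lists
#'
#' Two tab-separated columns \code{drug<TAB>target} (one row per pair) with a
#' header row.
#'
#' @param path path to the file.
#' @return named list of character vectors, one per drug.
#' @export
readTargets <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, quote = "",
                           comment.char = "", colClasses = "character")
  if (ncol(tab) < 2L)
    stop("target file needs columns drug<TAB>target")
  split(tab[[2L]], tab[[1L]])
}
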