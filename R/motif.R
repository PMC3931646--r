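#' @include AllGenerics.R
NULL

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.scanTriAspOne <- function(seq, strictness) {
  chars <- strsplit(seq, "")[[1]]
  if (!all(chars %in% .AA20))
    stop("non-amino-acid characters in sequence: ",
         paste(unique(chars[!chars %in% .AA20]), collapse = ", "))
  pat <- if (strictness == "D-only") "(?=D.{3}D.{5}D)"
         else "(?=[DE].{3}D.{5}[DE])"
  m <- gregexpr(pat, seq, perl = TRUE)[[1]]
  starts <- as.integer(m[m > 0])
  if (!length(starts))
    return(data.frame(p1 = integer(), p2 = integer(), p3 = integer(),
                      context = character(), mode = character()))
  data.frame(p1 = starts, p2 = starts + 4L, p3 = starts + 10L,
             context = substring(seq, starts, starts + 10L),
             mode = strictness)
}

#' @rdname scanTriAsp
#' @param strictness "D-only" (Asp required at all three positions) or
#'   "allow-E-flanks" (Glu accepted at the two flanking positions i and
#'   i+10, as in the related Kv channels; the central position must be
#'   Asp)
#' @details The Tri-Asp motif is the conserved 11-residue S2 span with
#'   acidic residues at spacing (i, i+4, i+10) — e.g. Asp252/256/262 in
#'   the canine B3 subunit and Asp221/225/231 in canine A3. All
#'   (possibly overlapping) hits are reported, in the input sequence's
#'   own 1-based coordinates.
#' @export
setMethod("scanTriAsp", "character", function(x,
    strictness = c("D-only", "allow-E-flanks")) {
  strictness <- match.arg(strictness)
  ids <- if (!is.null(names(x))) names(x)
         else sprintf("seq%d", seq_along(x))
  out <- do.call(rbind, lapply(seq_along(x), function(i) {
    h <- .scanTriAspOne(toupper(x[[i]]), strictness)
    if (nrow(h)) cbind(seq_id = ids[i], h)
    else cbind(seq_id = character(), h)
  }))
  if (is.null(out))
    out <- data.frame(seq_id = character(), p1 = integer(),
                      p2 = integer(), p3 = integer(),
                      context = character(), mode = character())
  rownames(out) <- NULL
  out
})

#' @rdname scanTriAsp
#' @export
setMethod("scanTriAsp", "AAStringSet", function(x,
    strictness = c("D-only", "allow-E-flanks")) {
  v <- as.character(x)
  if (is.null(names(v))) names(v) <- sprintf("seq%d", seq_along(v))
  scanTriAsp(v, strictness = match.arg(strictness))
})

#' Write motif hits as TSV
#'
#' @param hits data.frame from \code{\link{scanTriAsp}}
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeMotifHits <- function(hits, path) {
  utils::write.table(hits[c("seq_id", "p1", "p2", "p3", "mode")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
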