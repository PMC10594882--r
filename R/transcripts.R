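#' Construct a transcript model
#'
#' A minimal exon-level transcript representation sufficient for premature
#' termination codon (PTC) placement: ordered exons, a CDS interval in genomic
#' coordinates, and optionally a per-exon inclusion fraction (percent spliced
#' in, PSI) used by exon-mask repertoire constraints such as the TTN
#' adult-cardiac-isoform filter.
#'
#' @param transcript_id Transcript identifier.
#' @param gene HGNC gene symbol.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends 1-based inclusive genomic intervals, in
#'   genomic order, non-overlapping.
#' @param cds_start,cds_end Genomic CDS boundaries (start < end regardless of
#'   strand), inside the exon span.
#' @param exon_inclusion Optional numeric vector in `[0, 1]`, one value per
#'   exon in genomic order.
#' @return An object of class `g2p_transcript`.
#' @export
transcript_model <- function(transcript_id, gene, strand, exon_starts, exon_ends,
                             cds_start, cds_end, exon_inclusion = NULL) {
  stopifnot(strand %in% c("+", "-"),
            length(exon_starts) == length(exon_ends),
            all(exon_starts <= exon_ends))
  ord <- order(exon_starts)
  exon_starts <- exon_starts[ord]; exon_ends <- exon_ends[ord]
  if (length(exon_starts) > 1 &&
      any(exon_starts[-1] <= exon_ends[-length(exon_ends)]))
    stop("exons overlap in transcript ", transcript_id)
  if (!is.null(exon_inclusion)) {
    stopifnot(length(exon_inclusion) == length(exon_starts),
              all(exon_inclusion >= 0 & exon_inclusion <= 1))
    exon_inclusion <- exon_inclusion[ord]
  }
  if (cds_start < min(exon_starts) || cds_end > max(exon_ends) ||
      cds_start > cds_end)
    stop("CDS outside exon span in transcript ", transcript_id)
  structure(list(transcript_id = transcript_id, gene = gene, strand = strand,
                 exon_starts = as.integer(exon_starts),
                 exon_ends = as.integer(exon_ends),
                 cds_start = as.integer(cds_start),
                 cds_end = as.integer(cds_end),
                 exon_inclusion = exon_inclusion),
            class = "g2p_transcript")
}

#' @export
print.g2p_transcript <- function(x, ...) {
  cat(sprintf("<g2p_transcript> %s (%s, %s strand): %d exon(s), CDS %d-%d\n",
              x$transcript_id, x$gene, x$strand, length(x$exon_starts),
              x$cds_start, x$cds_end))
  invisible(x)
}

# internal: per-exon coding intervals in genomic order, clipped to the CDS.
coding_exons <- function(tm) {
  s <- pmax(tm$exon_starts, tm$cds_start)
  e <- pmin(tm$exon_ends, tm$cds_end)
  keep <- s <= e
  data.frame(exon = which(keep), start = s[keep], end = e[keep])
}

# internal: map a genomic position to a 1-based coding offset (5'->3' in
# transcript orientation).  Intronic positions are projected to the coding
# offset of the nearest exonic base on their 5' side (transcript sense), which
# is the relevant side for splice-site disruption.  Returns NA outside the CDS
# span.
coding_offset <- function(tm, pos) {
  ce <- coding_exons(tm)
  if (nrow(ce) == 0) return(NA_real_)
  lens <- ce$end - ce$start + 1
  if (tm$strand == "+") {
    before <- cumsum(c(0, lens))[-(nrow(ce) + 1)]
    for (i in seq_len(nrow(ce))) {
      if (pos >= ce$start[i] && pos <= ce$end[i])
        return(before[i] + (pos - ce$start[i]) + 1)
    }
    # intronic: offset of last coding base 5' of pos
    past <- which(ce$end < pos)
    if (length(past)) return(sum(lens[past])) else return(NA_real_)
  } else {
    ord <- rev(seq_len(nrow(ce)))           # 5'->3' is decreasing genomic
    before <- cumsum(c(0, lens[ord]))[seq_len(nrow(ce))]
    for (k in seq_along(ord)) {
      i <- ord[k]
      if (pos >= ce$start[i] && pos <= ce$end[i])
        return(before[k] + (ce$end[i] - pos) + 1)
    }
    past <- which(ce$start > pos)           # exons 5' of pos on minus strand
    if (length(past)) return(sum(lens[past])) else return(NA_real_)
  }
}

# internal: exon index (transcript 5'->3' order) containing a genomic
# position; NA when intronic/outside.
exon_rank_of <- function(tm, pos) {
  n <- length(tm$exon_starts)
  hit <- which(pos >= tm$exon_starts & pos <= tm$exon_ends)
  if (!length(hit)) return(NA_integer_)
  if (tm$strand == "+") hit[1] else (n - hit[1] + 1L)
}

# internal: inclusion fraction of the exon containing pos (NA when no PSI
# annotation or intronic position).
inclusion_at <- function(tm, pos) {
  if (is.null(tm$exon_inclusion)) return(NA_real_)
  hit <- which(pos >= tm$exon_starts & pos <= tm$exon_ends)
  if (!length(hit)) return(NA_real_)
  tm$exon_inclusion[hit[1]]
}

#' Mirror a transcript model onto the opposite strand
#'
#' Produces a transcript with identical 5'->3' geometry on the opposite
#' strand, reflecting all coordinates about a genomic axis.  Used by the
#' strand-symmetry property tests of the NMD classifier: a variant reflected
#' the same way must classify identically.
#'
#' @param tm A `g2p_transcript`.
#' @param axis Genomic reflection constant; position `p` maps to `axis - p`.
#' @return A `g2p_transcript` on the opposite strand.
#' @export
mirror_transcript <- function(tm, axis = 10000000L) {
  transcript_model(
    transcript_id = paste0(tm$transcript_id, "_mirror"),
    gene = tm$gene,
    strand = if (tm$strand == "+") "-" else "+",
    exon_starts = axis - tm$exon_ends,
    exon_ends = axis - tm$exon_starts,
    cds_start = axis - tm$cds_end,
    cds_end = axis - tm$cds_start,
    exon_inclusion = tm$exon_inclusion)
}

#' Read/write toy transcript tables
#'
#' The fixture transcript format is a TSV with one row per exon:
#' `transcript_id, gene, strand, exon_start, exon_end, cds_start, cds_end,
#' inclusion` (inclusion may be empty).
#'
#' @param path File path.
#' @return `read_transcripts`: a named list of `g2p_transcript` keyed by
#'   transcript id. `write_transcripts`: `path`, invisibly.
#' @export
read_transcripts <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  need <- c("transcript_id", "gene", "strand", "exon_start", "exon_end",
            "cds_start", "cds_end", "inclusion")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("transcript table missing column(s): ", paste(missing, collapse = ", "))
  out <- lapply(split(df, df$transcript_id), function(d) {
    incl <- suppressWarnings(as.numeric(d$inclusion))
    transcript_model(d$transcript_id[1], d$gene[1], d$strand[1],
                     as.integer(d$exon_start), as.integer(d$exon_end),
                     as.integer(d$cds_start[1]), as.integer(d$cds_end[1]),
                     exon_inclusion = if (all(is.na(incl))) NULL else incl)
  })
  out
}

#' @rdname read_transcripts
#' @param transcripts Named list of `g2p_transcript`.
#' @export
write_transcripts <- function(transcripts, path) {
  rows <- unlist(lapply(transcripts, function(tm) {
    incl <- if (is.null(tm$exon_inclusion)) rep("", length(tm$exon_starts))
            else format(tm$exon_inclusion, trim = TRUE)
    paste(tm$transcript_id, tm$gene, tm$strand, tm$exon_starts, tm$exon_ends,
          tm$cds_start, tm$cds_end, incl, sep = "\t")
  }))
  writeLines(c("transcript_id\tgene\tstrand\texon_start\texon_end\tcds_start\tcds_end\tinclusion",
               rows), path)
  invisible(path)
}
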