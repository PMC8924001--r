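#' Transcript models
#'
#' A transcript model is one representative transcript per gene, resolved to
#' transcript orientation, with a three-way segmentation into 5' UTR, CDS and
#' 3' UTR. All coordinates are 0-based half-open in transcript space: the 5'
#' UTR is `[0, cds_start)`, the CDS `[cds_start, cds_end)` and the 3' UTR
#' `[cds_end, length)`. Downstream code is therefore strand-free.
#'
#' @param transcript_id,gene_id Character vectors of identifiers.
#' @param sequence Character vector of transcript sequences (DNA alphabet;
#'   `U` is accepted and stored as `T`).
#' @param cds_start,cds_end Integer CDS bounds, 0-based half-open.
#' @return A `data.table` of class `transcript_models` with columns
#'   `transcript_id`, `gene_id`, `sequence`, `length`, `cds_start`,
#'   `cds_end`.
#' @export
transcript_models <- function(transcript_id, gene_id, sequence,
                              cds_start, cds_end) {
  sequence <- gsub("U", "T", toupper(sequence), fixed = TRUE)
  dt <- data.table(
    transcript_id = as.character(transcript_id),
    gene_id = as.character(gene_id),
    sequence = sequence,
    length = nchar(sequence),
    cds_start = as.integer(cds_start),
    cds_end = as.integer(cds_end)
  )
  validate_transcript_models(dt)
  setattr(dt, "class", c("transcript_models", class(dt)))
  dt[]
}

validate_transcript_models <- function(dt) {
  if (anyDuplicated(dt$transcript_id))
    stop("duplicated transcript_id", call. = FALSE)
  if (anyDuplicated(dt$gene_id))
    stop("duplicated gene_id: expected one transcript per gene",
         call. = FALSE)
  bad <- dt[cds_start < 0 | cds_start >= cds_end | cds_end > length]
  if (nrow(bad))
    stop("invalid CDS bounds for: ",
         paste(head(bad$transcript_id, 5), collapse = ", "), call. = FALSE)
  frame <- dt[(cds_end - cds_start) %% 3L != 0L]
  if (nrow(frame))
    stop("CDS length not a multiple of 3 for: ",
         paste(head(frame$transcript_id, 5), collapse = ", "),
         call. = FALSE)
  invisible(dt)
}

region_sequence <- function(models, region = c("utr5", "cds", "utr3")) {
  region <- match.arg(region)
  switch(region,
    utr5 = substr(models$sequence, 1L, models$cds_start),
    cds  = substr(models$sequence, models$cds_start + 1L, models$cds_end),
    utr3 = substr(models$sequence, models$cds_end + 1L, models$length)
  )
}

#' Region lengths of transcript models
#'
#' @param models A `transcript_models` table.
#' @return A long `data.table` with columns `transcript_id`, `region`
#'   (`exon`, `utr5`, `cds`, `utr3`) and `length` (nt). `exon` is the whole
#'   transcript.
#' @export
region_lengths <- function(models) {
  rbindlist(list(
    models[, .(transcript_id, region = "exon", length = length)],
    models[, .(transcript_id, region = "utr5", length = cds_start)],
    models[, .(transcript_id, region = "cds", length = cds_end - cds_start)],
    models[, .(transcript_id, region = "utr3", length = length - cds_end)]
  ))
}

#' Write / read transcript sequences as FASTA
#'
#' @param models A `transcript_models` table.
#' @param path Output FASTA path.
#' @return `write_transcript_fasta` returns `path` invisibly;
#'   `read_transcript_fasta` returns a named character vector of sequences.
#' @export
write_transcript_fasta <- function(models, path) {
  seqs <- Biostrings::DNAStringSet(
    setNames(models$sequence, models$transcript_id))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_transcript_fasta
#' @export
read_transcript_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
}

#' Write / read transcript-space annotation as BED12
#'
#' The annotation is stored in transcript space: one BED12 record per
#' transcript with the transcript id as chromosome name, a single block
#' spanning the transcript, and the thick interval marking the CDS.
#'
#' @param models A `transcript_models` table.
#' @param path BED12 file path.
#' @param fasta Path to the matching transcript FASTA.
#' @param gene_ids Optional named character vector mapping transcript ids to
#'   gene ids; by default the transcript id doubles as the gene id.
#' @return `read_transcript_bed` returns a `transcript_models` table.
#' @export
write_transcript_bed <- function(models, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = models$transcript_id,
    ranges = IRanges::IRanges(1L, models$length),
    strand = "+"
  )
  S4Vectors::mcols(gr)$name <- models$transcript_id
  S4Vectors::mcols(gr)$score <- 0L
  S4Vectors::mcols(gr)$thick <-
    IRanges::IRanges(models$cds_start + 1L, models$cds_end)
  S4Vectors::mcols(gr)$blocks <-
    IRanges::IRangesList(lapply(models$length,
                                function(l) IRanges::IRanges(1L, l)))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_transcript_bed
#' @export
read_transcript_bed <- function(path, fasta, gene_ids = NULL) {
  gr <- rtracklayer::import(path, format = "bed")
  seqs <- read_transcript_fasta(fasta)
  tid <- S4Vectors::mcols(gr)$name
  thick <- S4Vectors::mcols(gr)$thick
  if (is.null(thick))
    stop("BED file lacks thickStart/thickEnd (need BED12)", call. = FALSE)
  missing <- setdiff(tid, names(seqs))
  if (length(missing))
    stop("transcripts absent from FASTA: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  gid <- if (is.null(gene_ids)) tid else unname(gene_ids[tid])
  transcript_models(
    transcript_id = tid,
    gene_id = gid,
    sequence = seqs[tid],
    cds_start = IRanges::start(thick) - 1L,
    cds_end = IRanges::end(thick)
  )
}

#' Read transcript models from a genome-space GTF
#'
#' Exon and CDS features are mapped into transcript coordinates (exons
#' ordered 5' to 3' on the annotated strand) and the transcript sequence is
#' taken from `fasta` by transcript id, so all downstream computation is
#' strand-free. Stop codons annotated outside the CDS feature are not
#' added back; the CDS interval is used exactly as annotated.
#'
#' @param path GTF file with `transcript_id` and `gene_id` attributes.
#' @param fasta Transcript FASTA (ids must match `transcript_id`).
#' @return A `transcript_models` table.
#' @export
read_transcript_gtf <- function(path, fasta) {
  gr <- rtracklayer::import(path, format = "gtf")
  seqs <- read_transcript_fasta(fasta)
  md <- S4Vectors::mcols(gr)
  dt <- data.table(
    type = as.character(md$type),
    transcript_id = as.character(md$transcript_id),
    gene_id = as.character(md$gene_id),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  exons <- dt[type == "exon"]
  cds <- dt[type == "CDS"]
  if (!nrow(exons) || !nrow(cds))
    stop("GTF must contain exon and CDS features", call. = FALSE)
  one <- function(tid) {
    ex <- exons[transcript_id == tid]
    cd <- cds[transcript_id == tid]
    minus <- ex$strand[1] == "-"
    ex <- ex[order(start, decreasing = minus)]
    cum <- cumsum(c(0L, ex$end - ex$start + 1L))
    ## map a genomic position to transcript coordinate (0-based)
    to_tx <- function(gpos) {
      i <- which(gpos >= ex$start & gpos <= ex$end)
      if (!length(i)) stop("CDS position outside exons for ", tid,
                           call. = FALSE)
      if (minus) cum[i] + (ex$end[i] - gpos) else cum[i] + (gpos - ex$start[i])
    }
    gstart <- if (minus) max(cd$end) else min(cd$start)
    gend <- if (minus) min(cd$start) else max(cd$end)
    list(transcript_id = tid, gene_id = ex$gene_id[1],
         cds_start = to_tx(gstart), cds_end = to_tx(gend) + 1L)
  }
  recs <- rbindlist(lapply(unique(exons$transcript_id), one))
  transcript_models(
    transcript_id = recs$transcript_id,
    gene_id = recs$gene_id,
    sequence = seqs[recs$transcript_id],
    cds_start = recs$cds_start,
    cds_end = recs$cds_end
  )
}
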