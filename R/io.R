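#' Read and write binned profiles as SEG
#'
#' SEG on disk is tab-separated with a header
#' (`sample`, `chrom`, `start`, `end`, `num_mark`, `seg_mean`) and
#' 1-based inclusive coordinates; in memory profiles use 0-based
#' half-open coordinates, so `start` gains 1 on write and loses 1 on
#' read. One SEG file can hold many samples; [read_seg()] returns a
#' named list of `cnv_profile` objects with arms annotated from the
#' supplied genome table.
#'
#' @param profiles a `cnv_profile` or named list of them.
#' @param path file path.
#' @param genome per-arm table as from [default_genome()] used to
#'   annotate arms on read.
#' @return [read_seg()]: named list of `cnv_profile`; [write_seg()]:
#'   the path, invisibly.
#' @export
write_seg <- function(profiles, path) {
  if (inherits(profiles, "cnv_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    data.frame(sample = attr(p, "sample_id"),
               chrom = p$chrom, start = p$start + 1, end = p$end,
               num_mark = 1L, seg_mean = p$log2_ratio,
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_seg
#' @export
read_seg <- function(path, genome = default_genome()) {
  seg <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "seg_mean")
  if (!all(need %in% names(seg))) {
    stop_invalid("SEG file must have columns ", paste(need, collapse = ", "))
  }
  mk_profile <- function(d, id) {
    prof <- data.frame(chrom = d$chrom, start = d$start - 1, end = d$end,
                       log2_ratio = d$seg_mean, stringsAsFactors = FALSE)
    mid <- (prof$start + prof$end) / 2
    arm <- rep(NA_character_, nrow(prof))
    for (i in seq_len(nrow(genome))) {
      sel <- prof$chrom == genome$chrom[i] & mid >= genome$start[i] &
        mid < genome$end[i]
      arm[sel] <- genome$arm_label[i]
    }
    prof$arm <- arm
    rownames(prof) <- NULL  # file row order is preserved
    structure(prof, class = c("cnv_profile", "data.frame"), sample_id = id)
  }
  ids <- unique(seg$sample)
  out <- lapply(ids, function(id) mk_profile(seg[seg$sample == id, ], id))
  names(out) <- ids
  out
}

#' Read a BED interval file
#'
#' Standard 0-based half-open BED; only the first three (plus optional
#' name) columns are used.
#'
#' @param path file path.
#' @return data.frame with `chrom`, `start`, `end` and, if present,
#'   `name`.
#' @export
read_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    comment.char = "#")
  if (ncol(bed) < 3) stop_invalid("BED file needs at least 3 columns")
  names(bed)[1:3] <- c("chrom", "start", "end")
  if (ncol(bed) >= 4) names(bed)[4] <- "name"
  bed[, seq_len(min(ncol(bed), 4))]
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

read_counts_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}
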