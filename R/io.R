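# Readers and writers for the file dialects used across the pipeline:
# FASTA genomes (Biostrings), BED peak tracks and bedGraph methylation
# (rtracklayer), tab-separated on-target / detection / candidate tables,
# model checkpoints and dataset manifests. All intervals are exposed
# 0-based half-open; rtracklayer's 1-based GRanges are shifted on entry
# and exit.

ONTARGET_COLUMNS <- c("chrom", "start", "end", "strand", "sequence23",
                      "cell_type", "experiment_id", "raw_efficacy")

#' Read a (multi-)FASTA file
#'
#' @param path FASTA file path.
#' @return named character vector of uppercase sequences; names are the
#'   first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) stop("malformed FASTA in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' Read epigenetic tracks from a directory
#'
#' Track files follow the `<cell_type>.<mark>.bed` / `.bedgraph` naming
#' convention with marks `ctcf`, `dnase`, `h3k4me3` (BED3+) and `rrbs`
#' (bedGraph beta values). Intervals are returned 0-based half-open.
#'
#' @param paths character vector of track file paths, or a single
#'   directory to scan.
#' @return nested list `tracks[[cell_type]][[mark]]` of data frames with
#'   `chrom`, `start`, `end`, `value`.
#' @export
read_tracks <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(bed|bedgraph)$",
                        full.names = TRUE, ignore.case = TRUE)
  }
  out <- list()
  for (p in paths) {
    base <- basename(p)
    parts <- strsplit(base, ".", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      stop("track file name must look like <cell_type>.<mark>.bed[graph]: ",
           base, call. = FALSE)
    }
    ct <- parts[1]; mark <- tolower(parts[2]); ext <- tolower(parts[3])
    .validate_intervals(p)
    gr <- rtracklayer::import(p, format = if (ext == "bed") "BED" else "bedGraph")
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     value = if (ext == "bed") 1 else
                       as.numeric(gr$score %||% 1),
                     stringsAsFactors = FALSE)
    out[[ct]][[mark]] <- df
  }
  out
}

# cheap structural check so malformed rows are reported with line numbers
.validate_intervals <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nchar(ln) || grepl("^(track|browser|#)", ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop("line ", i, " of ", basename(path), ": fewer than 3 fields",
           call. = FALSE)
    }
    st <- suppressWarnings(as.numeric(f[2]))
    en <- suppressWarnings(as.numeric(f[3]))
    if (is.na(st) || is.na(en) || en <= st) {
      stop("line ", i, " of ", basename(path),
           ": invalid interval (end <= start)", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Write epigenetic tracks to a directory
#'
#' @param tracks nested list as produced by [gen_tracks()]/[read_tracks()].
#' @param dir output directory (created if needed).
#' @return character vector of written paths.
#' @export
write_tracks <- function(tracks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (ct in names(tracks)) {
    for (mark in names(tracks[[ct]])) {
      df <- tracks[[ct]][[mark]]
      ext <- if (mark == "rrbs") "bedgraph" else "bed"
      path <- file.path(dir, paste0(ct, ".", mark, ".", ext))
      cols <- if (mark == "rrbs") df[, c("chrom", "start", "end", "value")]
              else df[, c("chrom", "start", "end")]
      utils::write.table(cols, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      written <- c(written, path)
    }
  }
  invisible(written)
}

#' Read an on-target record table (TSV)
#'
#' Required columns: `chrom`, `start`, `end`, `strand`, `sequence23`,
#' `cell_type`, `experiment_id`, `raw_efficacy`; optional `binary_label`
#' and `normalized_label`.
#'
#' @param path TSV path (header required, tab-delimited, UTF-8).
#' @return data frame of on-target records.
#' @export
read_ontarget_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(ONTARGET_COLUMNS, names(df))
  if (length(missing)) {
    stop("on-target table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Write an on-target record table (TSV)
#'
#' @param records data frame of on-target records.
#' @param path output path.
#' @export
write_ontarget_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an off-target detection table (TSV)
#'
#' Columns: `guide_id`, `chrom`, `start`, `strand`, and optionally
#' `assay`, `indel_frequency`.
#'
#' @param path TSV path.
#' @return data frame of detections.
#' @export
read_detections <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("guide_id", "chrom", "start", "strand")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("detection table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname read_detections
#' @param detections data frame of detections.
#' @param path output path.
#' @export
write_detections <- function(detections, path) {
  utils::write.table(detections, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write enumerated candidates as BED6+
#'
#' Columns: chrom, start, end, name (guide id), score (mismatch count),
#' strand, site sequence, mismatch-profile string.
#'
#' @param candidates data frame from [enumerate_candidates()] with a
#'   `guide_id` column.
#' @param path output path.
#' @export
write_candidates <- function(candidates, path) {
  df <- data.frame(candidates$chrom, candidates$start, candidates$end,
                   candidates$guide_id, candidates$mismatch_count,
                   candidates$strand, candidates$site_sequence,
                   candidates$mismatch_profile)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_candidates
#' @export
read_candidates <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "guide_id", "mismatch_count",
                 "strand", "site_sequence", "mismatch_profile")
  df$mismatch_profile[is.na(df$mismatch_profile)] <- ""
  df
}

# ---- checkpoints -----------------------------------------------------------

CHECKPOINT_VERSION <- 1L

#' Save / load a model checkpoint
#'
#' Checkpoints carry the architecture configuration, all parameters and
#' normalization statistics, the training seed and a data-schema hash;
#' loading a checkpoint whose schema differs from this package's encoding
#' is rejected, so a model can never silently score differently encoded
#' inputs. A round trip reproduces predictions bit-exactly.
#'
#' @param model a `crispr_parent`, `crispr_ontarget` or `crispr_offtarget`
#'   object.
#' @param path checkpoint file path.
#' @return `save_checkpoint` returns the path invisibly; `load_checkpoint`
#'   returns the model.
#' @export
save_checkpoint <- function(model, path) {
  if (!inherits(model, c("crispr_parent", "crispr_ontarget",
                         "crispr_offtarget"))) {
    stop("not a fitted model", call. = FALSE)
  }
  saveRDS(list(version = CHECKPOINT_VERSION, class = class(model)[1],
               schema = model$schema, seed = model$config$seed,
               model = unclass(model)),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("unreadable checkpoint ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.list(obj) || is.null(obj$version) || is.null(obj$model)) {
    stop("not a model checkpoint: ", path, call. = FALSE)
  }
  if (obj$version > CHECKPOINT_VERSION) {
    stop("checkpoint version ", obj$version, " is newer than supported",
         call. = FALSE)
  }
  if (!identical(obj$schema, schema_hash())) {
    stop("checkpoint schema '", obj$schema,
         "' does not match this package's encoding schema", call. = FALSE)
  }
  structure(obj$model, class = obj$class)
}

# ---- manifests -------------------------------------------------------------

#' Write / read a dataset manifest
#'
#' Records the generating configuration, seed, per-file row counts and
#' md5 checksums of a written dataset; loading verifies the checksums.
#'
#' @param files named character vector of file paths.
#' @param config list of generator settings (stored verbatim).
#' @param seed integer seed used for generation.
#' @param path manifest JSON path.
#' @return `write_manifest` returns the path invisibly; `read_manifest`
#'   the manifest list (after checksum verification).
#' @export
write_manifest <- function(files, config, seed, path) {
  entries <- lapply(files, function(f) {
    list(path = basename(f), md5 = unname(tools::md5sum(f)),
         bytes = file.info(f)$size)
  })
  jsonlite::write_json(list(schema_version = 1L, seed = seed,
                            config = config, files = entries),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path)
  dir <- dirname(path)
  for (e in m$files) {
    f <- file.path(dir, e$path)
    if (!file.exists(f)) stop("manifest file missing: ", e$path, call. = FALSE)
    if (!identical(unname(tools::md5sum(f)), e$md5)) {
      stop("checksum mismatch for ", e$path, call. = FALSE)
    }
  }
  m
}
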