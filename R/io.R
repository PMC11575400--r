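MUTATION_COLS <- c("line_id", "condition", "position", "mtype", "size",
                   "gene", "gene_length", "effect", "frequency", "censored",
                   "genome_size")
EFFECT_LEVELS <- c("synonymous", "nonsynonymous", "frameshift", "nonsense",
                   "intergenic")

validate_mutation_table <- function(tbl) {
  missing_cols <- setdiff(MUTATION_COLS, names(tbl))
  if (length(missing_cols)) {
    stop("mutation table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(tbl)) {
    if (any(!tbl$effect %in% EFFECT_LEVELS)) {
      stop("unknown effect class: ",
           paste(setdiff(tbl$effect, EFFECT_LEVELS), collapse = ", "),
           call. = FALSE)
    }
    if (any(!tbl$mtype %in% c("SNP", "INS", "DEL"))) {
      stop("mtype must be SNP, INS or DEL", call. = FALSE)
    }
    if (any(tbl$frequency < 0 | tbl$frequency > 1)) {
      stop("frequencies must lie in [0, 1]", call. = FALSE)
    }
    if (any(tbl$size < 1)) stop("mutation size must be >= 1 bp", call. = FALSE)
    if (any(tbl$position < 1 | tbl$position > tbl$genome_size)) {
      stop("positions must lie in 1..genome_size", call. = FALSE)
    }
    bad_len <- tbl$gene != "intergenic" &
      (is.na(tbl$gene_length) | tbl$gene_length <= 0)
    if (any(bad_len)) {
      stop("genic records need a positive gene_length", call. = FALSE)
    }
  }
  tibble::as_tibble(tbl)[MUTATION_COLS]
}

#' Write / read a mutation table as tidy TSV
#'
#' Lossless tab-separated round-trip of the mutation-table columns.
#' Censored frequencies (reported in source tables as e.g. "<5%") are
#' written as their coded numeric value with `censored = TRUE`.
#'
#' @param table Mutation table tibble.
#' @param path File path.
#' @return `write_mutation_tsv` returns `path` invisibly;
#'   `read_mutation_tsv` returns the validated tibble.
#' @export
write_mutation_tsv <- function(table, path) {
  tbl <- validate_mutation_table(table)
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' @rdname write_mutation_tsv
#' @export
read_mutation_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           line_id = "c", condition = "c", position = "i",
                           mtype = "c", size = "i", gene = "c",
                           gene_length = "d", effect = "c", frequency = "d",
                           censored = "l", genome_size = "d"))
  validate_mutation_table(tbl)
}

#' Read a minimal GenomeDiff file into a mutation table
#'
#' Parses the SNP/INS/DEL mutation entries of a GenomeDiff file (the
#' breseq/GDtools interchange format). Evidence lines (RA/MC/JC) and other
#' entry types are skipped (a count is reported via a message). Attributes
#' used: `frequency` (either "0.356" or "35.6%" dialect; missing means a
#' consensus call, coded 1.0), `gene_name`, `gene_length`, `snp_type`
#' (synonymous/nonsynonymous/nonsense; intergenic when absent and no gene
#' is named). Positions are 1-based and are never shifted.
#'
#' @param path GenomeDiff file; must start with `#=GENOME_DIFF`.
#' @param genome_size Genome size in bp (GenomeDiff carries none).
#' @param line_id,condition Metadata stamped on the records.
#' @return A validated mutation table tibble.
#' @export
read_genomediff <- function(path, genome_size, line_id = basename(path),
                            condition = "unknown") {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1], "#=GENOME_DIFF")) {
    stop("not a GenomeDiff file (missing #=GENOME_DIFF header): ", path,
         call. = FALSE)
  }
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(trimws(body))]
  skipped <- 0L
  recs <- list()
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    type <- f[1]
    if (!type %in% c("SNP", "INS", "DEL")) {
      skipped <- skipped + 1L
      next
    }
    if (length(f) < 6) stop("malformed GenomeDiff entry: ", ln, call. = FALSE)
    # columns: type, id, parent-ids, seq_id, position, payload, attributes
    pos <- suppressWarnings(as.integer(f[5]))
    if (is.na(pos) || pos < 1) {
      stop("malformed position in GenomeDiff line: ", ln, call. = FALSE)
    }
    attrs <- f[-(1:6)]
    attrs <- attrs[grepl("=", attrs, fixed = TRUE)]
    kv <- strsplit(attrs, "=", fixed = TRUE)
    keys <- vapply(kv, `[[`, character(1), 1)
    vals <- vapply(kv, function(p) paste(p[-1], collapse = "="), character(1))
    att <- stats::setNames(vals, keys)

    freq <- att["frequency"]
    frequency <- if (is.na(freq)) 1.0 else parse_frequency(freq)
    gene <- if (!is.na(att["gene_name"])) att["gene_name"] else "intergenic"
    gene_length <- suppressWarnings(as.numeric(att["gene_length"]))
    snp_type <- att["snp_type"]
    effect <- if (type == "SNP") {
      if (!is.na(snp_type) && snp_type %in% EFFECT_LEVELS) snp_type
      else if (gene == "intergenic") "intergenic" else "nonsynonymous"
    } else {
      if (gene == "intergenic") "intergenic" else "frameshift"
    }
    size <- switch(type,
                   SNP = 1L,
                   INS = nchar(f[6]),
                   DEL = suppressWarnings(as.integer(f[6])))
    if (is.na(size) || size < 1) {
      stop("malformed payload in GenomeDiff line: ", ln, call. = FALSE)
    }
    recs[[length(recs) + 1L]] <- tibble::tibble(
      line_id = line_id, condition = condition, position = pos,
      mtype = type, size = as.integer(size), gene = unname(gene),
      gene_length = if (gene == "intergenic") NA_real_ else unname(gene_length),
      effect = unname(effect), frequency = unname(frequency),
      censored = FALSE, genome_size = genome_size)
  }
  if (skipped) message(skipped, " non-mutation GenomeDiff entries skipped")
  if (!length(recs)) {
    out <- empty_mutation_table()
  } else {
    out <- dplyr::bind_rows(recs)
  }
  validate_mutation_table(out)
}

# accepts "0.356", "35.6%", "35.60%"
parse_frequency <- function(s) {
  s <- trimws(s)
  if (endsWith(s, "%")) {
    v <- suppressWarnings(as.numeric(sub("%$", "", s))) / 100
  } else {
    v <- suppressWarnings(as.numeric(s))
  }
  if (is.na(v) || v < 0 || v > 1) {
    stop("cannot parse frequency: ", s, call. = FALSE)
  }
  v
}

#' Read a competition-assay TSV
#'
#' Columns: `genotype_i`, `genotype_j`, `condition`, `initial_freq_i`,
#' `replicate`, `N0_i`, `Nf_i`, `N0_j`, `Nf_j`, `duration_days`. All
#' densities must be positive; duplicate (condition, frequency, replicate)
#' keys are rejected.
#'
#' @param path File path.
#' @return A validated assay tibble.
#' @export
read_assays_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  req <- c("genotype_i", "genotype_j", "condition", "initial_freq_i",
           "replicate", "N0_i", "Nf_i", "N0_j", "Nf_j", "duration_days")
  missing_cols <- setdiff(req, names(tbl))
  if (length(missing_cols)) {
    stop("assay TSV lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dens <- as.matrix(tbl[c("N0_i", "Nf_i", "N0_j", "Nf_j")])
  bad <- which(!is.finite(dens) | dens <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-positive density in assay row ", bad[1, 1], call. = FALSE)
  }
  if (any(tbl$duration_days <= 0)) {
    stop("duration_days must be > 0", call. = FALSE)
  }
  key <- paste(tbl$condition, tbl$initial_freq_i, tbl$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate (condition, frequency, replicate) key in assay TSV",
         call. = FALSE)
  }
  tibble::as_tibble(tbl)
}

#' Write / read a transfer series as tidy TSV
#'
#' Columns `day`, `label`, `cfu_per_ml`, `censored`.
#'
#' @param series Transfer-series tibble from [run_serial_transfers()].
#' @param path File path.
#' @export
write_transfer_tsv <- function(series, path) {
  stopifnot(all(c("day", "label", "cfu_per_ml", "censored") %in% names(series)))
  readr::write_tsv(series[c("day", "label", "cfu_per_ml", "censored")], path)
  invisible(path)
}

#' @rdname write_transfer_tsv
#' @export
read_transfer_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(day = "i", label = "c",
                                                 cfu_per_ml = "d",
                                                 censored = "l"))
  class(out) <- c("xf_transfer_series", class(out))
  out
}

#' Read a wide plate-reader CSV into a long curve tibble
#'
#' First column is time, remaining columns are wells. The time unit is
#' auto-detected from the header: a name containing `min` is divided by 60
#' (hours are the package unit). Optional metadata (per-well `blank` and
#' `R0`) comes from a YAML sidecar; blanks are subtracted here, defaulting
#' to the plate-wide minimum of the first reading when no blank is given.
#'
#' @param path CSV path.
#' @param meta_path Optional YAML sidecar: top-level `default` block and/or
#'   per-well blocks with `blank`, `R0`, `replicate_of`.
#' @return A list: `plate` (long tibble `well`, `time`, `od`,
#'   blank-corrected) and `meta` (tibble `well`, `blank`, `R0`,
#'   `replicate_of`).
#' @export
read_plate_csv <- function(path, meta_path = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         name_repair = "minimal")
  if (ncol(raw) < 2) stop("plate CSV needs a time column and wells", call. = FALSE)
  if (anyDuplicated(names(raw))) {
    stop("duplicated well column name in plate CSV", call. = FALSE)
  }
  if (anyNA(raw)) stop("missing cells in plate CSV", call. = FALSE)
  tname <- names(raw)[1]
  time <- raw[[1]]
  if (grepl("min", tname, ignore.case = TRUE)) time <- time / 60
  if (length(time) < 10) stop("need at least 10 time points", call. = FALSE)
  if (any(diff(time) <= 0)) stop("non-monotone time column", call. = FALSE)
  wells <- names(raw)[-1]

  meta <- tibble::tibble(well = wells, blank = NA_real_, R0 = NA_real_,
                         replicate_of = NA_character_)
  if (!is.null(meta_path)) {
    y <- yaml::read_yaml(meta_path)
    dflt <- y$default %||% list()
    for (i in seq_along(wells)) {
      w <- wells[i]
      entry <- y[[w]] %||% list()
      meta$blank[i] <- entry$blank %||% dflt$blank %||% NA_real_
      meta$R0[i] <- entry$R0 %||% dflt$R0 %||% NA_real_
      meta$replicate_of[i] <- entry$replicate_of %||% NA_character_
    }
  }
  plate_min <- min(as.numeric(raw[1, -1, drop = TRUE]))
  ods <- raw[-1]
  long <- tibble::tibble(
    well = rep(wells, each = length(time)),
    time = rep(time, times = length(wells)),
    od = unlist(ods, use.names = FALSE))
  blanks <- ifelse(is.na(meta$blank), plate_min, meta$blank)
  long$od <- long$od - blanks[match(long$well, meta$well)]
  long <- dplyr::arrange(long, .data$well, .data$time)
  list(plate = tibble::as_tibble(long), meta = meta)
}

#' Write a set of growth curves as a wide plate CSV
#'
#' Inverse of [read_plate_csv()]: one `time_h` column plus one column per
#' well.
#'
#' @param plate Long tibble with `well`, `time`, `od`.
#' @param path CSV path.
#' @export
write_plate_csv <- function(plate, path) {
  stopifnot(all(c("well", "time", "od") %in% names(plate)))
  wide <- tidyr::pivot_wider(plate, id_cols = "time", names_from = "well",
                             values_from = "od")
  names(wide)[1] <- "time_h"
  readr::write_csv(wide, path)
  invisible(path)
}
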