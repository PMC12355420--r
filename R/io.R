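#' Read per-cell cytometry events into a tidy event table
#'
#' Reads event-level flow-cytometry data from a delimited text file or an
#' FCS 3.0/3.1 file and returns one row per cell with the three canonical
#' channels `gfp` (expression reporter), `lc3` (autophagosome marker
#' immunostain) and `viability` (dead-cell dye, e.g. 7-AAD), plus sample
#' metadata columns.
#'
#' @param path Path to the input file.
#' @param format `"csv"` for delimited text (comma or tab, auto-detected) or
#'   `"fcs"` for FCS 3.0/3.1.
#' @param channel_map Named character vector mapping source channel/column
#'   names to the canonical names, e.g.
#'   `c("FITC-A" = "gfp", "APC-A" = "lc3", "PerCP-A" = "viability")`.
#'   `NULL` (default) assumes the canonical names are already present.
#' @param transform_policy Intensity transform applied after reading:
#'   `"floor"` (default) floors non-positive values at epsilon = smallest
#'   positive recorded value / 10 so that geometric means are defined;
#'   `"identity"` leaves values untouched; `"arcsinh"` applies
#'   `asinh(x / cofactor)`.
#' @param cofactor Arcsinh cofactor (ignored unless
#'   `transform_policy = "arcsinh"`); default 150, a common cytometry choice.
#' @param sample_id,construct,treatment,replicate Sample metadata recorded on
#'   every event row. `treatment` must be `"untreated"` or `"bafa1"`.
#'
#' @return A tibble with columns `sample_id`, `construct`, `treatment`,
#'   `replicate`, `gfp`, `lc3`, `viability`. The applied transform policy is
#'   recorded in the `"transform_policy"` attribute.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(gfp = c(10, 200), lc3 = c(50, 80),
#'                      viability = c(30, 40)), f, row.names = FALSE)
#' read_events(f, sample_id = "s1", construct = "WT")
read_events <- function(path,
                        format = c("csv", "fcs"),
                        channel_map = NULL,
                        transform_policy = c("floor", "identity", "arcsinh"),
                        cofactor = 150,
                        sample_id = basename(path),
                        construct = NA_character_,
                        treatment = c("untreated", "bafa1"),
                        replicate = 1L) {
  format <- match.arg(format)
  transform_policy <- match.arg(transform_policy)
  treatment <- match.arg(treatment)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))

  raw <- switch(format,
    csv = read_events_csv(path),
    fcs = as_tibble(as.data.frame(read_fcs(path)$data))
  )

  if (!is.null(channel_map)) {
    hit <- names(raw) %in% names(channel_map)
    names(raw)[hit] <- unname(channel_map[names(raw)[hit]])
  }

  required <- c("gfp", "lc3", "viability")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    abort(sprintf("missing required channel(s): %s",
                  paste(missing, collapse = ", ")),
          class = "fluxscreen_channel_error")
  }

  raw <- raw[required]
  for (ch in required) {
    v <- raw[[ch]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      abort(sprintf("non-numeric event in channel '%s' at row %s", ch,
                    paste(head(bad, 5L), collapse = ", ")),
            class = "fluxscreen_parse_error")
    }
    if (any(!is.finite(v))) {
      abort(sprintf("non-finite intensity in channel '%s' at row %d",
                    ch, which(!is.finite(v))[1L]),
            class = "fluxscreen_parse_error")
    }
  }

  out <- tibble(
    sample_id = sample_id,
    construct = construct,
    treatment = treatment,
    replicate = as.integer(replicate),
    gfp = raw$gfp, lc3 = raw$lc3, viability = raw$viability
  )
  out <- apply_transform(out, transform_policy, cofactor)
  fs_log("read %d events from %s", nrow(out), path)
  out
}

read_events_csv <- function(path) {
  readr::read_delim(path,
    delim = guess_delim(path), show_col_types = FALSE,
    progress = FALSE, trim_ws = TRUE
  )
}

# comma/tab auto-detection on the header line
guess_delim <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (stringr::str_count(header, "\t") >= stringr::str_count(header, ",")) "\t" else ","
}

apply_transform <- function(events, policy, cofactor = 150) {
  ch <- c("gfp", "lc3", "viability")
  if (policy == "floor") {
    for (k in ch) {
      v <- events[[k]]
      pos <- v[v > 0]
      eps <- if (length(pos)) min(pos) / 10 else .Machine$double.eps
      events[[k]] <- pmax(v, eps)
    }
  } else if (policy == "arcsinh") {
    for (k in ch) events[[k]] <- asinh(events[[k]] / cofactor)
  }
  attr(events, "transform_policy") <- policy
  if (policy == "arcsinh") attr(events, "cofactor") <- cofactor
  events
}

#' Read an FCS 3.0/3.1 file
#'
#' Minimal list-mode reader for the FCS 3.0 and 3.1 container: parses the
#' HEADER and TEXT segments and decodes the DATA segment for
#' `$MODE L` (list mode) with `$DATATYPE` `F` (32-bit float), `D` (64-bit
#' float) or `I` (unsigned integers of `$PnB` bits). Spillover/compensation
#' is not applied and FCS writing is out of scope.
#'
#' @param path Path to the FCS file.
#' @return A list with `data` (numeric matrix, one column per parameter,
#'   named by `$PnN`), `keywords` (named character vector from the TEXT
#'   segment) and `version`.
#' @export
read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  header <- rawToChar(readBin(con, "raw", 58L))
  version <- trimws(substr(header, 1L, 6L))
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    abort(sprintf("unsupported FCS version '%s' (need FCS3.0/FCS3.1)", version))
  }
  off <- function(a, b) as.numeric(trimws(substr(header, a, b)))
  text_beg <- off(11, 18); text_end <- off(19, 26)
  data_beg <- off(27, 34); data_end <- off(35, 42)

  seek(con, text_beg)
  text <- rawToChar(readBin(con, "raw", text_end - text_beg + 1L))
  delim <- substr(text, 1L, 1L)
  parts <- strsplit(substring(text, 2L), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2L == 1L) parts <- parts[-length(parts)]
  kw <- setNames(parts[seq(2L, length(parts), 2L)],
                 trimws(parts[seq(1L, length(parts), 2L)]))

  # DATA offsets may live in TEXT when too large for the header slots
  if (data_beg == 0) data_beg <- as.numeric(kw[["$BEGINDATA"]])
  if (data_end == 0) data_end <- as.numeric(kw[["$ENDDATA"]])

  npar <- as.integer(kw[["$PAR"]])
  ntot <- as.integer(kw[["$TOT"]])
  dtype <- kw[["$DATATYPE"]]
  mode <- kw[["$MODE"]] %||% "L"
  if (mode != "L") abort("only list-mode ($MODE L) FCS data is supported")
  byteord <- kw[["$BYTEORD"]]
  endian <- if (startsWith(byteord, "1")) "little" else "big"

  seek(con, data_beg)
  nvals <- npar * ntot
  vals <- switch(dtype,
    F = readBin(con, "numeric", nvals, size = 4L, endian = endian),
    D = readBin(con, "numeric", nvals, size = 8L, endian = endian),
    I = {
      bits <- as.integer(kw[[sprintf("$P%dB", 1L)]])
      readBin(con, "integer", nvals, size = bits %/% 8L,
              signed = bits < 32L, endian = endian)
    },
    abort(sprintf("unsupported $DATATYPE '%s'", dtype))
  )
  m <- matrix(as.numeric(vals), ncol = npar, byrow = TRUE)
  colnames(m) <- vapply(seq_len(npar), function(i) {
    kw[[sprintf("$P%dN", i)]] %||% sprintf("P%d", i)
  }, character(1))
  list(data = m, keywords = kw, version = version)
}

#' Read a plate screening table
#'
#' Reads a delimited per-well table of raw screening signals (one row per
#' drug or vehicle well) into a validated tibble. Category annotations are
#' split into a `category_tags` list-column.
#'
#' Required columns: `drug_id`, `drug_name`, `well`, `is_vehicle`,
#' `cellmask_raw` (whole-cell stain, proxy for cell number / viability),
#' `sdc1_raw` (in-cell-western GAG core-protein reporter). Optional:
#' `nluc_raw` (luciferase protein-stability reporter; `NA` where the plate
#' lacks it), `plate` (defaults to a single plate), `category`
#' (tag string, split on `tag_delim`).
#'
#' @param path Path to a CSV/TSV file (delimiter auto-detected).
#' @param tag_delim Delimiter separating category tags within the
#'   `category` field (default `";"`).
#' @return A tibble of screen records.
#' @export
read_screen_table <- function(path, tag_delim = ";") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_delim(path,
    delim = guess_delim(path),
    show_col_types = FALSE, progress = FALSE, trim_ws = TRUE
  )
  required <- c("drug_id", "drug_name", "well", "is_vehicle",
                "cellmask_raw", "sdc1_raw")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    abort(sprintf("screen table missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (!"plate" %in% names(raw)) raw$plate <- "plate1"
  if (!"nluc_raw" %in% names(raw)) raw$nluc_raw <- NA_real_
  if (!"category" %in% names(raw)) raw$category <- ""
  raw$is_vehicle <- as.logical(raw$is_vehicle)
  validate_screen_records(
    mutate(raw, category_tags = strsplit(
      dplyr::coalesce(as.character(.data$category), ""), tag_delim, fixed = TRUE
    ))
  )
}

validate_screen_records <- function(records) {
  sig <- c("cellmask_raw", "sdc1_raw", "nluc_raw")
  for (k in sig) {
    v <- records[[k]]
    if (any(v < 0, na.rm = TRUE)) {
      abort(sprintf("negative signal in column '%s'", k))
    }
  }
  drugs <- filter(records, !.data$is_vehicle)
  dup <- drugs |>
    group_by(.data$plate, .data$drug_id) |>
    summarise(n = dplyr::n(), .groups = "drop") |>
    filter(.data$n > 1L)
  if (nrow(dup)) {
    abort(sprintf("duplicate drug_id within a plate: %s",
                  paste(unique(dup$drug_id), collapse = ", ")))
  }
  veh_clash <- intersect(
    unique(drugs$drug_id),
    unique(records$drug_id[records$is_vehicle])
  )
  if (length(veh_clash)) {
    abort(sprintf("vehicle wells reuse library drug_id(s): %s",
                  paste(veh_clash, collapse = ", ")))
  }
  as_tibble(records)
}

#' Construct a screening funnel report
#'
#' A funnel report is an ordered stage table: each stage records how many
#' entries came in, how many were retained, how many were excluded, and the
#' identifiers on each side. Two invariants are enforced: conservation
#' (`n_retained + n_excluded == n_in` at every stage) and chaining (stage
#' k+1 starts from stage k's retained set).
#'
#' @param stages A data frame / tibble with columns `stage_name`, `n_in`,
#'   `n_retained`, `n_excluded` and list-columns `retained_ids`,
#'   `excluded_ids`.
#' @param annotations Optional named list of extra counts carried alongside
#'   the funnel (e.g. single-criterion hit counts).
#' @return A `funnel_report` tibble.
#' @export
funnel_report <- function(stages, annotations = list()) {
  if (nrow(stages) == 0L) abort("empty funnel")
  stages <- as_tibble(stages)
  needed <- c("stage_name", "n_in", "n_retained", "n_excluded",
              "retained_ids", "excluded_ids")
  missing <- setdiff(needed, names(stages))
  if (length(missing)) {
    abort(sprintf("funnel stages missing field(s): %s",
                  paste(missing, collapse = ", ")))
  }
  stages$n_in <- as.integer(stages$n_in)
  stages$n_retained <- as.integer(stages$n_retained)
  stages$n_excluded <- as.integer(stages$n_excluded)
  if (any(stages$n_retained + stages$n_excluded != stages$n_in)) {
    abort("funnel conservation violated: n_retained + n_excluded != n_in")
  }
  if (nrow(stages) > 1L) {
    chained <- stages$n_in[-1L] == stages$n_retained[-nrow(stages)]
    if (!all(chained)) abort("funnel chaining violated: stage k+1 n_in != stage k n_retained")
  }
  structure(stages, annotations = annotations,
            class = c("funnel_report", class(stages)))
}

#' Write / read a funnel report
#'
#' Serializes a [funnel_report()] to JSON or TSV; `read_funnel_report()`
#' reads it back, re-validating both funnel invariants, so a
#' write-read round trip is lossless.
#'
#' @param report A `funnel_report`.
#' @param path Output (input) file path.
#' @param format `"json"` or `"tsv"`. For TSV the id lists are joined
#'   with `";"`.
#' @return `write_funnel_report()` returns `path` invisibly;
#'   `read_funnel_report()` returns a `funnel_report`.
#' @export
write_funnel_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "funnel_report"))
  if (format == "json") {
    payload <- list(
      stages = purrr::pmap(report, function(stage_name, n_in, n_retained,
                                            n_excluded, retained_ids,
                                            excluded_ids, ...) {
        list(stage_name = stage_name, n_in = n_in, n_retained = n_retained,
             n_excluded = n_excluded,
             retained_ids = as.character(retained_ids),
             excluded_ids = as.character(excluded_ids))
      }),
      annotations = attr(report, "annotations") %||% list()
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else {
    flat <- mutate(as_tibble(report),
      retained_ids = purrr::map_chr(.data$retained_ids, paste, collapse = ";"),
      excluded_ids = purrr::map_chr(.data$excluded_ids, paste, collapse = ";")
    )
    readr::write_tsv(flat, path)
  }
  invisible(path)
}

#' @rdname write_funnel_report
#' @export
read_funnel_report <- function(path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- jsonlite::read_json(path)
    stages <- purrr::map_dfr(payload$stages, function(s) {
      tibble(
        stage_name = s$stage_name,
        n_in = as.integer(s$n_in),
        n_retained = as.integer(s$n_retained),
        n_excluded = as.integer(s$n_excluded),
        retained_ids = list(as.character(unlist(s$retained_ids))),
        excluded_ids = list(as.character(unlist(s$excluded_ids)))
      )
    })
    ann <- payload$annotations %||% list()
    funnel_report(stages, annotations = ann)
  } else {
    flat <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    split_ids <- function(x) {
      lapply(x, function(s) {
        if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, ";", fixed = TRUE)[[1]]
      })
    }
    funnel_report(mutate(flat,
      retained_ids = split_ids(.data$retained_ids),
      excluded_ids = split_ids(.data$excluded_ids)
    ))
  }
}

#' Read a cycloheximide-chase decay time course
#'
#' Expects columns `time_h` (hours since translation block, the `pre`
#' sample at 0), `value` (relative band intensity) and optionally
#' `series_id` and `replicate`.
#'
#' @param path CSV/TSV path (delimiter auto-detected).
#' @return A tibble with columns `series_id`, `replicate`, `time_h`, `value`.
#' @export
read_decay_course <- function(path) {
  raw <- readr::read_delim(path, delim = guess_delim(path),
                           show_col_types = FALSE, progress = FALSE)
  if (!all(c("time_h", "value") %in% names(raw))) {
    abort("decay course needs columns 'time_h' and 'value'")
  }
  if (!"series_id" %in% names(raw)) raw$series_id <- "series1"
  if (!"replicate" %in% names(raw)) raw$replicate <- 1L
  if (any(raw$time_h < 0)) abort("negative time_h in decay course")
  select(as_tibble(raw), "series_id", "replicate", "time_h", "value")
}

#' Read a genotype count table
#'
#' Expects columns `n_wt`, `n_het`, `n_hom` (non-negative integers) and
#' optionally `group_label`.
#'
#' @param path CSV/TSV path.
#' @return A tibble of genotype counts, one row per group.
#' @export
read_genotype_counts <- function(path) {
  raw <- readr::read_delim(path, delim = guess_delim(path),
                           show_col_types = FALSE, progress = FALSE)
  needed <- c("n_wt", "n_het", "n_hom")
  if (!all(needed %in% names(raw))) {
    abort("genotype table needs columns n_wt, n_het, n_hom")
  }
  if (!"group_label" %in% names(raw)) raw$group_label <- "pooled"
  counts <- raw[needed]
  if (any(unlist(counts) < 0) || any(unlist(counts) != round(unlist(counts)))) {
    abort("genotype counts must be non-negative integers")
  }
  if (any(rowSums(counts) < 1)) abort("each genotype group needs total >= 1")
  as_tibble(raw)
}

#' Read a qPCR Ct table
#'
#' Standards need columns `dilution` (relative quantity of the serially
#' diluted reference sample) and `ct`; unknowns need `sample` and `ct`.
#'
#' @param path CSV/TSV path.
#' @return A tibble.
#' @export
read_ct_table <- function(path) {
  raw <- readr::read_delim(path, delim = guess_delim(path),
                           show_col_types = FALSE, progress = FALSE)
  if (!"ct" %in% names(raw)) abort("Ct table needs a 'ct' column")
  as_tibble(raw)
}

#' Read a key-value analysis configuration file
#'
#' Thin YAML reader for pipeline configuration (gate boundaries, screen
#' thresholds, seeds, transform policy). Documented keys mirror the
#' arguments of [gate_config()] and [screen_config()].
#'
#' @param path YAML file path.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config not found: %s", path))
  yaml::read_yaml(path)
}
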