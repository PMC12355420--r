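# fixtures are built in code at test time; no binary files ship with the repo

# minimal FCS 3.0 writer (list mode, float32, little-endian) used only to
# exercise the reader
write_test_fcs <- function(path, data, channel_names = colnames(data)) {
  data <- as.matrix(data)
  npar <- ncol(data)
  ntot <- nrow(data)
  delim <- "/"
  kw <- c(
    "$DATATYPE", "F", "$MODE", "L", "$BYTEORD", "1,2,3,4",
    "$PAR", npar, "$TOT", ntot,
    "$BEGINDATA", "0", "$ENDDATA", "0"
  )
  for (i in seq_len(npar)) {
    kw <- c(kw, sprintf("$P%dN", i), channel_names[i],
            sprintf("$P%dB", i), "32",
            sprintf("$P%dE", i), "0,0",
            sprintf("$P%dR", i), "262144")
  }
  text <- paste0(delim, paste(kw, collapse = delim), delim)
  text_beg <- 58L
  text_end <- text_beg + nchar(text) - 1L
  data_beg <- text_end + 1L
  data_end <- data_beg + 4L * npar * ntot - 1L
  fmt8 <- function(x) sprintf("%8d", x)
  header <- paste0(
    "FCS3.0    ",
    fmt8(text_beg), fmt8(text_end), fmt8(data_beg), fmt8(data_end),
    fmt8(0), fmt8(0)
  )
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.numeric(t(data)), con, size = 4L, endian = "little")
  invisible(path)
}

# tiny in-memory event table with canonical channels
make_events <- function(gfp, lc3, viability = rep(10, length(gfp)),
                        treatment = "untreated", replicate = 1L,
                        construct = "WT") {
  tibble::tibble(
    sample_id = paste0(construct, "_", treatment),
    construct = construct, treatment = treatment,
    replicate = as.integer(replicate),
    gfp = gfp, lc3 = lc3, viability = viability
  )
}

# untreated/bafa1 pair split from a generated table
split_arms <- function(events) {
  list(
    untreated = dplyr::filter(events, treatment == "untreated"),
    bafa1 = dplyr::filter(events, treatment == "bafa1")
  )
}

paper_named_exclusions <- c("Andrographolide", "Apigenin",
                            "Berberine sulfate", "Harmine hydrochloride")
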