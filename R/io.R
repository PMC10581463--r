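guidekit_version <- function() {
  as.character(utils::packageVersion("guidekit"))
}

# 32-bit FNV-1a hash of a string, as 8 hex digits; used to stamp output
# files with a config fingerprint
fnv1a32 <- function(x) {
  h <- 0x811c9dc5
  for (b in utf8ToInt(x)) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # 32-bit modular multiply by the FNV prime 16777619 = 2^24 + 403
    h <- ((h * 403) %% 2^32 + (h %% 256) * 2^24) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write a table as TSV with a metadata header
#'
#' Prepends comment lines recording the tool version, RNG seed and a
#' fingerprint of the run configuration, then the column header and
#' tab-separated rows.
#'
#' @param df Data.frame to write.
#' @param path Output path.
#' @param seed Seed to record (NA if the step is deterministic).
#' @param config Named list recorded as a JSON fingerprint.
#' @return `path`, invisibly.
#' @export
write_tsv_meta <- function(df, path, seed = NA, config = list()) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# guidekit ", guidekit_version()),
    paste0("# seed=", seed),
    paste0("# config_hash=", fnv1a32(as.character(cfg_json)))), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a guidekit TSV (metadata comment lines are skipped)
#'
#' @param path Input path.
#' @return Data.frame.
#' @export
read_tsv_meta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
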