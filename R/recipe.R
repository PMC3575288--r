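# Golden Gate assembly recipes. A TALEN arm of n RVDs is assembled from
# n-1 position-specific module plasmids plus a "last half repeat"
# plasmid carrying the final RVD; the kit layout (slot count per array,
# plasmid naming, supported repeat range) lives in an editable YAML file
# so kit revisions need no code change. Volumes are computed from a
# local reagent-concentration table.

#' Read a Golden Gate kit layout
#'
#' @param path YAML file with keys `min_repeats`, `max_repeats`,
#'   `slots_per_array`, `module_pattern` (with `{rvd}` / `{slot}`
#'   placeholders) and `last_repeat_pattern` (with `{rvd}`). Default is
#'   the packaged layout modeled on the common 10-slot array kits.
#' @return A `kit_layout` list.
#' @export
read_kit_layout <- function(path = system.file("extdata", "kit_layout.yaml",
                                               package = "talenforge")) {
  lay <- yaml::read_yaml(path)
  needed <- c("min_repeats", "max_repeats", "slots_per_array",
              "module_pattern", "last_repeat_pattern")
  missing <- setdiff(needed, names(lay))
  if (length(missing) > 0) {
    stop("kit layout missing field(s): ", paste(missing, collapse = ", "))
  }
  stopifnot(lay$min_repeats >= 2, lay$max_repeats >= lay$min_repeats,
            lay$slots_per_array >= 1)
  structure(lay, class = "kit_layout")
}

fill_pattern <- function(pattern, rvd, slot = NULL) {
  out <- gsub("{rvd}", rvd, pattern, fixed = TRUE)
  if (!is.null(slot)) out <- gsub("{slot}", slot, out, fixed = TRUE)
  out
}

#' Pick module plasmids for an RVD string
#'
#' Positions `1..n-1` map to array-module plasmids named by slot (the
#' position within each array, cycling every `slots_per_array`) and RVD;
#' the final RVD maps to the last-half-repeat plasmid.
#'
#' @param rvds Character vector of RVD codes (or a tab-delimited string).
#' @param layout A `kit_layout` from [read_kit_layout()].
#' @return Data frame with `position`, `rvd`, `plasmid`.
#' @export
pick_modules <- function(rvds, layout = read_kit_layout()) {
  stopifnot(inherits(layout, "kit_layout"))
  if (length(rvds) == 1L && grepl("\t", rvds)) {
    rvds <- strsplit(rvds, "\t", fixed = TRUE)[[1]]
  }
  bad <- setdiff(unique(rvds), names(BASE_OF_RVD))
  if (length(bad) > 0) stop("unknown RVD code(s): ", paste(bad, collapse = ", "))
  n <- length(rvds)
  if (n < layout$min_repeats || n > layout$max_repeats) {
    stop("RVD count ", n, " outside the kit-supported range ",
         layout$min_repeats, "-", layout$max_repeats)
  }
  plasmid <- character(n)
  for (pos in seq_len(n - 1L)) {
    slot <- ((pos - 1L) %% layout$slots_per_array) + 1L
    plasmid[pos] <- fill_pattern(layout$module_pattern, rvds[pos], slot)
  }
  plasmid[n] <- fill_pattern(layout$last_repeat_pattern, rvds[n])
  data.frame(position = seq_len(n), rvd = rvds, plasmid = plasmid,
             stringsAsFactors = FALSE)
}

#' Read a reagent-concentration table
#'
#' @param path TSV or CSV with columns `plasmid` and `conc_ng_ul`
#'   (header optional for TSV). Concentrations must be positive.
#' @return Data frame with `plasmid`, `conc_ng_ul`.
#' @export
read_reagent_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  first <- readLines(path, n = 1L, warn = FALSE)
  has_header <- grepl("plasmid", first, ignore.case = TRUE)
  df <- utils::read.table(path, sep = sep, header = has_header,
                          stringsAsFactors = FALSE, comment.char = "#")
  df <- df[, 1:2]
  names(df) <- c("plasmid", "conc_ng_ul")
  df$conc_ng_ul <- as.numeric(df$conc_ng_ul)
  if (anyNA(df$conc_ng_ul) || any(df$conc_ng_ul <= 0)) {
    stop("reagent table has missing or non-positive concentrations")
  }
  df
}

#' Compute pipetting volumes for a pick list
#'
#' Volume per plasmid is `target_mass_ng / stock concentration`, rounded
#' to 0.1 µL. Volumes that round below the 0.1 µL pipetting floor are
#' clamped to 0.1 µL with a warning (dilute the stock instead).
#'
#' @param picks Data frame from [pick_modules()].
#' @param table Reagent table from [read_reagent_table()].
#' @param target_mass_ng Target DNA mass per module plasmid (default 75).
#' @return Data frame with `position`, `rvd`, `plasmid`, `mass_ng`,
#'   `volume_uL`.
#' @export
compute_volumes <- function(picks, table, target_mass_ng = 75) {
  stopifnot(target_mass_ng > 0)
  hit <- match(picks$plasmid, table$plasmid)
  if (anyNA(hit)) {
    stop("plasmid(s) missing from reagent table: ",
         paste(unique(picks$plasmid[is.na(hit)]), collapse = ", "))
  }
  conc <- table$conc_ng_ul[hit]
  vol <- floor(target_mass_ng / conc * 10 + 0.5) / 10
  under <- vol < 0.1
  if (any(under)) {
    warning("volume below the 0.1 uL pipetting floor for: ",
            paste(picks$plasmid[under], collapse = ", "),
            " (clamped; consider diluting the stock)")
    vol[under] <- 0.1
  }
  data.frame(position = picks$position, rvd = picks$rvd,
             plasmid = picks$plasmid, mass_ng = target_mass_ng,
             volume_uL = vol, stringsAsFactors = FALSE)
}

#' Full recipe for one TALEN arm
#'
#' Convenience wrapper: [pick_modules()] then [compute_volumes()].
#'
#' @inheritParams pick_modules
#' @inheritParams compute_volumes
#' @export
recipe_for_rvds <- function(rvds, table, layout = read_kit_layout(),
                            target_mass_ng = 75) {
  compute_volumes(pick_modules(rvds, layout), table, target_mass_ng)
}
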