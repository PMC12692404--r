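#' Condition registry
#'
#' An experimental condition (`ej`) bundles three phenotypic labels of the
#' assayed cell line: a doubling-time class (`dt`), the cell-line identity
#' (`ct`) and the microsatellite status (`mc`, `MSS` stable / `MSI`
#' unstable). `condition_registry()` validates a user table;
#' `default_condition_registry()` returns the seven colorectal-cancer
#' assay conditions used throughout the package examples.
#'
#' @param data Data frame with columns `condition_id`, `dt_label`,
#'   `ct_label`, `mc_label`.
#' @return A tibble of class `condition_registry`.
#' @export
condition_registry <- function(data) {
  need <- c("condition_id", "dt_label", "ct_label", "mc_label")
  if (!all(need %in% names(data))) {
    rlang::abort(paste0("registry needs columns: ",
                        paste(need, collapse = ", ")))
  }
  data <- as_tibble(data)[need]
  if (anyDuplicated(data$condition_id)) {
    rlang::abort("condition ids must be unique")
  }
  class(data) <- c("condition_registry", class(data))
  data
}

#' @rdname condition_registry
#' @export
default_condition_registry <- function() {
  condition_registry(tibble(
    condition_id = paste0("ej0", 1:7),
    dt_label = c("Slow growth", "Fast growth", "Fast growth", "Fast growth",
                 "Intermediate growth", "Intermediate growth", "Slow growth"),
    ct_label = c("HCC2998", "HT-29", "HCT 15", "HCT 116", "KM12", "SW620",
                 "COLO 205"),
    mc_label = c("MSS", "MSS", "MSI", "MSI", "MSI", "MSS", "MSS")
  ))
}

#' Attach condition labels to assay cases
#'
#' @param cases Tibble with a `condition_id` column.
#' @param registry A [condition_registry()].
#' @return `cases` with `dt`, `ct`, `mc` columns appended.
#' @export
expand_labels <- function(cases, registry) {
  stopifnot(inherits(registry, "condition_registry"))
  idx <- match(cases$condition_id, registry$condition_id)
  if (anyNA(idx)) {
    rlang::abort(paste0("condition id(s) not in registry: ",
                        paste(unique(cases$condition_id[is.na(idx)]),
                              collapse = ", ")))
  }
  cases |>
    mutate(dt = registry$dt_label[idx],
           ct = registry$ct_label[idx],
           mc = registry$mc_label[idx])
}

#' Curate raw assay records
#'
#' Applies the curation rules of the modeling workflow: records with
#' missing SMILES, activity values or unknown units are dropped;
#' multi-component or unparsable SMILES are dropped; molecules outside the
#' molar-mass window are dropped; duplicates per (molecule, condition) are
#' collapsed to the lowest GI50; the activity class is then assigned by the
#' threshold (`ACRC = +1` iff `GI50 <= threshold`).
#'
#' @param raw Data frame with columns `molecule_id`, `smiles`, `gi50_nm`,
#'   `condition_id` (optionally `gi50_unit` in nM/uM/M).
#' @param registry A [condition_registry()]; every `condition_id` must be
#'   registered.
#' @param threshold_nm Activity threshold in nM (default 1900).
#' @param mass_window Molar-mass window in g/mol (default `c(130, 854)`).
#' @return Tibble of curated cases (`molecule_id`, `smiles`, `gi50_nm`,
#'   `condition_id`, `molar_mass`, `ACRC`), deterministically ordered; the
#'   dropped records with reasons are attached as attribute `"rejected"`.
#' @export
curate_assays <- function(raw, registry = default_condition_registry(),
                          threshold_nm = 1900, mass_window = c(130, 854)) {
  need <- c("molecule_id", "smiles", "gi50_nm", "condition_id")
  if (!all(need %in% names(raw))) {
    rlang::abort(paste0("raw records need columns: ",
                        paste(need, collapse = ", ")))
  }
  stopifnot(inherits(registry, "condition_registry"))
  x <- as_tibble(raw)
  unknown <- setdiff(unique(x$condition_id), registry$condition_id)
  if (length(unknown)) {
    rlang::abort(paste0("condition id(s) not in registry: ",
                        paste(unknown, collapse = ", ")))
  }
  if ("gi50_unit" %in% names(x)) {
    fac <- unname(c(nM = 1, uM = 1e3, M = 1e9)[x$gi50_unit])
    x$gi50_nm <- x$gi50_nm * fac
    x$reason <- ifelse(is.na(fac), "unknown unit", NA_character_)
  } else {
    x$reason <- NA_character_
  }
  x <- x |>
    mutate(reason = case_when(
      !is.na(.data$reason) ~ .data$reason,
      is.na(.data$smiles) | !nzchar(trimws(.data$smiles)) ~ "missing SMILES",
      grepl(".", .data$smiles, fixed = TRUE) ~ "multi-component SMILES",
      is.na(.data$gi50_nm) ~ "missing activity value",
      .data$gi50_nm <= 0 ~ "non-positive activity value",
      TRUE ~ NA_character_
    ))
  ok <- is.na(x$reason)
  if (any(ok)) {
    mols <- x$smiles[ok][!duplicated(x$molecule_id[ok])]
    ids <- x$molecule_id[ok][!duplicated(x$molecule_id[ok])]
    graphs <- suppressWarnings(
      parse_molecules(mols, as.character(ids), on_error = "drop"))
    mass <- vapply(graphs, function(g) g$molar_mass, 1.0)
    mi <- match(as.character(x$molecule_id), names(mass))
    x$molar_mass <- unname(mass[mi])
  } else {
    x$molar_mass <- NA_real_
  }
  x <- x |>
    mutate(reason = case_when(
      !is.na(.data$reason) ~ .data$reason,
      is.na(.data$molar_mass) ~ "unparsable SMILES",
      .data$molar_mass < mass_window[1] |
        .data$molar_mass > mass_window[2] ~ "molar mass outside window",
      TRUE ~ NA_character_
    ))
  rejected <- filter(x, !is.na(.data$reason))
  kept <- x |>
    filter(is.na(.data$reason)) |>
    group_by(.data$molecule_id, .data$condition_id) |>
    slice_min(.data$gi50_nm, n = 1L, with_ties = FALSE) |>
    ungroup() |>
    mutate(ACRC = ifelse(.data$gi50_nm <= threshold_nm, 1L, -1L)) |>
    select("molecule_id", "smiles", "gi50_nm", "condition_id",
           "molar_mass", "ACRC") |>
    arrange(.data$molecule_id, .data$condition_id)
  if (nrow(rejected)) {
    inform(paste0(nrow(rejected), " record(s) rejected during curation"))
  }
  attr(kept, "rejected") <- rejected
  kept
}

#' Train/test split by the sorted 3:1 rule
#'
#' Cases are sorted by increasing GI50, then condition id, then molecule id
#' (a fixed tie-break); walking the sorted list in blocks of four, the
#' first three cases of each block go to the training set and the fourth to
#' the test set. A trailing partial block goes to training. The split is
#' deterministic.
#'
#' @param cases Curated cases (see [curate_assays()]).
#' @return `cases` with a `partition` column (`"train"` / `"test"`), in the
#'   sorted order.
#' @export
split_assays <- function(cases) {
  stopifnot(all(c("gi50_nm", "condition_id", "molecule_id") %in% names(cases)))
  out <- cases |>
    arrange(.data$gi50_nm, .data$condition_id, .data$molecule_id) |>
    mutate(partition = ifelse(dplyr::row_number() %% 4L == 0L,
                              "test", "train"))
  if (nrow(out) < 4L) {
    warn("fewer than 4 cases: all assigned to training")
    out$partition <- "train"
  }
  out
}
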