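#' Replicate-level observation tables
#'
#' The universal input to every analysis stage is a long-format table of
#' replicate-level trait observations keyed by MA treatment and line, with
#' additional parent/tetrad/spore keys for haploids derived by tetrad
#' dissection. Ancestor observations carry the treatment label `"ancestor"`
#' and a single pseudo-line: the ancestor has no line structure of its own,
#' and downstream variance comparisons impose the comparator treatment's
#' structure on it via [ancestor_pseudo_lines()].
#'
#' @param df data.frame with at least `treatment`, `line`, `trait`, `value`;
#'   optional `parent`, `tetrad`, `spore`, `replicate`. Missing key columns
#'   are added as `NA`; missing `replicate` is auto-numbered within key.
#' @return A validated `ma_obs` data.frame with columns
#'   `treatment, line, parent, tetrad, spore, trait, replicate, value`.
#' @export
observation_table <- function(df) {
  stopifnot(is.data.frame(df))
  names(df) <- tolower(names(df))
  required <- c("treatment", "line", "trait", "value")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("observation table lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  for (k in c("parent", "tetrad", "spore")) {
    if (!k %in% names(df)) df[[k]] <- NA_character_
    df[[k]] <- as.character(df[[k]])
    df[[k]][!is.na(df[[k]]) & df[[k]] == ""] <- NA_character_
  }
  df$treatment <- as.character(df$treatment)
  df$line <- as.character(df$line)
  df$trait <- as.character(df$trait)
  df$value <- as.numeric(df$value)
  if (!"replicate" %in% names(df) || all(is.na(df$replicate))) {
    key <- interaction(df$treatment, df$line, df$parent, df$tetrad,
                       df$spore, df$trait, drop = TRUE)
    df$replicate <- stats::ave(seq_len(nrow(df)), key, FUN = seq_along)
  }
  df$replicate <- as.integer(df$replicate)
  df <- df[, c("treatment", "line", "parent", "tetrad", "spore",
               "trait", "replicate", "value")]
  bad <- which(!is.finite(df$value))
  if (length(bad) > 0) {
    stop("non-finite value(s) at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  key <- do.call(paste, c(df[, c("treatment", "line", "parent", "tetrad",
                                 "spore", "trait", "replicate")],
                          sep = "\r"))
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop("duplicate observation key(s) at row(s): ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  class(df) <- c("ma_obs", "data.frame")
  df
}

#' @export
print.ma_obs <- function(x, ...) {
  cat(sprintf("ObservationTable: %d rows, %d trait(s), %d treatment(s)\n",
              nrow(x), length(unique(x$trait)), length(unique(x$treatment))))
  NextMethod()
}

#' Read an observation table from CSV
#'
#' Reads the long-format schema written by [write_observation_table()]
#' (`treatment,line,parent,tetrad,spore,trait,replicate,value`). Header
#' matching is case-insensitive and tolerates the common variants
#' `strain`/`ma_line` for `line` and `fitness`/`phenotype` for `value`,
#' so deposited tables of ancestor-centered fitness values load directly.
#'
#' @param path CSV file path.
#' @return An `ma_obs` table.
#' @export
read_observation_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  names(df) <- tolower(names(df))
  alias <- c(strain = "line", ma_line = "line", fitness = "value",
             phenotype = "value", time = "replicate", rep = "replicate")
  for (a in names(alias)) {
    if (a %in% names(df) && !alias[[a]] %in% names(df)) {
      names(df)[names(df) == a] <- alias[[a]]
    }
  }
  observation_table(df)
}

#' Write an observation table to CSV
#'
#' @param obs `ma_obs` table.
#' @param path output CSV path; inapplicable keys are written as empty fields.
#' @return `path`, invisibly.
#' @export
write_observation_table <- function(obs, path) {
  obs <- observation_table(obs)
  out <- as.data.frame(obs)
  for (k in c("parent", "tetrad", "spore")) out[[k]][is.na(out[[k]])] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Per-line trait means
#'
#' Line means weight lines equally regardless of replicate counts, matching
#' the convention used for all mean-change and line-mean likelihood analyses.
#'
#' @param obs `ma_obs` table (one or more traits/treatments).
#' @return data.frame with `treatment`, `line`, `trait`, `mean`, `n_rep`.
#' @export
line_means <- function(obs) {
  obs <- observation_table(obs)
  key <- interaction(obs$treatment, obs$line, obs$trait, drop = TRUE)
  agg <- do.call(rbind, lapply(split(obs, key), function(d) {
    data.frame(treatment = d$treatment[1], line = d$line[1],
               trait = d$trait[1], mean = mean(d$value), n_rep = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg[order(agg$treatment, agg$trait, agg$line), ]
}

# subset helper used throughout: one trait, optionally one treatment
obs_subset <- function(obs, trait = NULL, treatment = NULL) {
  if (!is.null(trait)) obs <- obs[obs$trait %in% trait, , drop = FALSE]
  if (!is.null(treatment)) obs <- obs[obs$treatment %in% treatment, , drop = FALSE]
  obs
}
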