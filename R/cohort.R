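#' Twin-pair cohorts
#'
#' A twin cohort is a data frame with one row per twin pair (the sampling
#' unit of the classical twin design) carrying a pair identifier, zygosity
#' (MZ or DZ), per-twin sex and age, and one pair of columns
#' \code{<trait>_1} / \code{<trait>_2} per declared trait. Binary traits are
#' coded 0/1; missing values are allowed per twin per trait. The trait
#' schema (binary vs continuous) and a free-text provenance string travel
#' with the object as attributes.
#'
#' @param data data frame with columns \code{pair_id}, \code{zygosity} and
#'   \code{<trait>_1}/\code{<trait>_2} for every trait in \code{traits};
#'   \code{sex1}, \code{sex2}, \code{age1}, \code{age2} are optional.
#' @param traits named character vector mapping trait name to \code{"binary"}
#'   or \code{"continuous"}.
#' @param provenance free-text description of where the data came from.
#' @return object of class \code{twin_cohort} (a data frame).
#' @examples
#' df <- data.frame(pair_id = c("p1", "p2"), zygosity = c("MZ", "DZ"),
#'                  asthma_1 = c(1L, 0L), asthma_2 = c(1L, NA))
#' co <- twin_cohort(df, traits = c(asthma = "binary"))
#' @export
twin_cohort <- function(data, traits, provenance = "user-supplied") {
  stopifnot(is.data.frame(data))
  if (is.null(names(traits)) || any(names(traits) == "") ||
      !all(traits %in% c("binary", "continuous")))
    stop("`traits` must be a named vector with values 'binary'/'continuous'")
  traits <- vapply(traits, identity, character(1))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  for (col in c("pair_id", "zygosity"))
    if (!col %in% names(data)) stop("missing mandatory column: ", col)

  data$pair_id <- as.character(data$pair_id)
  if (anyDuplicated(data$pair_id))
    stop("pair_id values must be unique; duplicated: ",
         paste(utils::head(unique(data$pair_id[duplicated(data$pair_id)]), 3),
               collapse = ", "))

  zyg <- toupper(trimws(as.character(data$zygosity)))
  bad <- which(!zyg %in% c("MZ", "DZ"))
  if (length(bad))
    stop("zygosity must be MZ or DZ; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (value '", data$zygosity[bad[1]], "')")
  data$zygosity <- zyg

  for (col in c("sex1", "sex2"))
    if (!col %in% names(data)) data[[col]] <- NA_character_
  for (col in c("age1", "age2")) {
    if (!col %in% names(data)) data[[col]] <- NA_real_
    data[[col]] <- as.numeric(data[[col]])
    neg <- which(!is.na(data[[col]]) & data[[col]] < 0)
    if (length(neg))
      stop("negative age in column ", col, ", row(s): ",
           paste(utils::head(neg, 5), collapse = ", "))
  }
  for (col in c("sex1", "sex2")) {
    s <- tolower(trimws(as.character(data[[col]])))
    s[is.na(s) | s == ""] <- "unknown"
    bad <- which(!s %in% c("male", "female", "unknown"))
    if (length(bad))
      stop("sex must be male/female/unknown in ", col, ", row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    data[[col]] <- s
  }

  for (tr in names(traits)) {
    for (j in 1:2) {
      col <- paste0(tr, "_", j)
      if (!col %in% names(data)) stop("missing trait column: ", col)
      v <- data[[col]]
      if (is.logical(v)) v <- as.integer(v)
      v <- as.numeric(v)
      if (traits[[tr]] == "binary") {
        bad <- which(!is.na(v) & !v %in% c(0, 1))
        if (length(bad))
          stop("binary trait '", tr, "' must be 0/1/missing; row(s): ",
               paste(utils::head(bad, 5), collapse = ", "))
        v <- as.integer(v)
      }
      data[[col]] <- v
    }
  }

  cols <- c("pair_id", "zygosity", "sex1", "sex2", "age1", "age2",
            as.vector(rbind(paste0(names(traits), "_1"),
                            paste0(names(traits), "_2"))))
  data <- data[, cols, drop = FALSE]
  rownames(data) <- NULL
  structure(data,
            trait_schema = traits,
            provenance = provenance,
            class = c("twin_cohort", "data.frame"))
}

#' @export
print.twin_cohort <- function(x, ...) {
  sch <- attr(x, "trait_schema")
  cat("Twin cohort:", nrow(x), "pairs (",
      sum(x$zygosity == "MZ"), "MZ /", sum(x$zygosity == "DZ"), "DZ )\n")
  cat("Traits:", paste(sprintf("%s [%s]", names(sch), sch), collapse = ", "),
      "\n")
  cat("Provenance:", attr(x, "provenance"), "\n")
  invisible(x)
}

trait_schema <- function(cohort) attr(cohort, "trait_schema")

trait_kind <- function(cohort, trait) {
  sch <- trait_schema(cohort)
  if (!trait %in% names(sch)) stop("unknown trait: ", trait)
  sch[[trait]]
}

# n x 2 matrix of per-twin values for one trait
trait_matrix <- function(cohort, trait) {
  trait_kind(cohort, trait)
  cbind(cohort[[paste0(trait, "_1")]], cohort[[paste0(trait, "_2")]])
}

#' Read a twin cohort from CSV
#'
#' Columns: \code{pair_id}, \code{zygosity}, optional \code{sex1}/\code{sex2}/
#' \code{age1}/\code{age2}, and \code{<trait>_1}/\code{<trait>_2} per declared
#' trait. Empty fields are missing values. Rows violating the schema raise an
#' error naming the offending row.
#'
#' @param path CSV file path.
#' @param traits named character vector (trait name -> "binary"/"continuous").
#' @return a \code{\link{twin_cohort}}.
#' @export
read_twin_cohort <- function(path, traits) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  twin_cohort(df, traits, provenance = path)
}

#' Write a twin cohort to CSV
#'
#' Deterministic column order (\code{pair_id}, \code{zygosity}, sex, age,
#' then trait columns); missing values are written as empty fields so the
#' file round-trips through \code{\link{read_twin_cohort}}.
#'
#' @param cohort a \code{\link{twin_cohort}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_twin_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "twin_cohort"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Restrict to pairs with complete data on a trait
#'
#' Keeps the pairs in which both twins have a non-missing value for
#' \code{trait} ("intact" pairs). Model-fitting on binary traits and all
#' concordance statistics operate on complete pairs.
#'
#' @param cohort a \code{\link{twin_cohort}}.
#' @param trait trait name.
#' @return the sub-cohort of complete pairs.
#' @export
complete_pairs <- function(cohort, trait) {
  m <- trait_matrix(cohort, trait)
  keep <- !is.na(m[, 1]) & !is.na(m[, 2])
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "trait_schema") <- trait_schema(cohort)
  attr(out, "provenance") <- paste0(attr(cohort, "provenance"),
                                    " | complete pairs on ", trait)
  class(out) <- c("twin_cohort", "data.frame")
  out
}

#' Swap twin 1 and twin 2 in every pair
#'
#' Twin order within a pair is arbitrary; every statistic in the package is
#' invariant under this relabeling (exercised by the test suite).
#'
#' @param cohort a \code{\link{twin_cohort}}.
#' @return the relabeled cohort.
#' @export
swap_twins <- function(cohort) {
  out <- cohort
  for (base in c("sex", "age", names(trait_schema(cohort)))) {
    c1 <- paste0(base, if (base %in% c("sex", "age")) "1" else "_1")
    c2 <- paste0(base, if (base %in% c("sex", "age")) "2" else "_2")
    tmp <- out[[c1]]; out[[c1]] <- out[[c2]]; out[[c2]] <- tmp
  }
  out
}

# subset rows, keeping attributes
subset_cohort <- function(cohort, keep, note = NULL) {
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "trait_schema") <- trait_schema(cohort)
  prov <- attr(cohort, "provenance")
  attr(out, "provenance") <- if (is.null(note)) prov else paste0(prov, " | ", note)
  class(out) <- c("twin_cohort", "data.frame")
  out
}

# minimum-data guard used by the model fitters
check_both_zygosities <- function(cohort) {
  if (!any(cohort$zygosity == "MZ") || !any(cohort$zygosity == "DZ"))
    stop("model fitting requires at least one MZ and one DZ pair")
  invisible(TRUE)
}
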