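#' Discrete morphological character matrices
#'
#' A `character_matrix` stores a taxa-by-characters matrix of discrete
#' morphological observations. Each cell is a *state set*: a fully observed
#' cell holds one integer state, a polymorphic cell the listed states, and
#' a missing (`?`) or inapplicable (`-`) cell the full state set of its
#' character. States are coded `0..k-1`; the per-character state count `k`
#' is the maximum observed state plus one (at least 2) unless overridden.
#'
#' @param cells list of length `nchar`; element `j` is a list of `ntaxa`
#'   integer vectors giving the 0-based state set observed for each taxon.
#' @param taxa character vector of unique taxon labels.
#' @param state_count optional integer vector of per-character state counts
#'   `k`; defaults to `max(observed) + 1`, floored at 2.
#' @param ordered logical vector flagging ordered characters (instantaneous
#'   change restricted to adjacent states); default all unordered.
#' @param partition character vector of per-character partition labels, or
#'   `NULL` for a single unnamed partition.
#' @return An object of class `character_matrix`.
#' @export
character_matrix <- function(cells, taxa, state_count = NULL, ordered = NULL,
                             partition = NULL) {
  nc <- length(cells)
  nt <- length(taxa)
  if (anyDuplicated(taxa)) stop("duplicate taxon names")
  if (is.null(state_count)) {
    state_count <- vapply(cells, function(col) {
      obs <- unlist(col)
      max(2L, max(obs) + 1L)
    }, integer(1))
  }
  if (is.null(ordered)) ordered <- rep(FALSE, nc)
  if (is.null(partition)) partition <- rep("all", nc)
  m <- structure(
    list(taxa = as.character(taxa), nchar = nc,
         cells = cells, state_count = as.integer(state_count),
         ordered = as.logical(ordered), partition = as.character(partition)),
    class = "character_matrix")
  validate_character_matrix(m)
  m
}

#' Validate a character matrix
#'
#' Checks that every cell is a non-empty subset of its character's state
#' set, that dimensions agree and that partition labels cover every
#' character. With `require_variable = TRUE` it also demands that every
#' character shows at least two distinct fully observed states across
#' taxa, the coding assumption under which the acquisition-bias (Mkv)
#' correction is valid.
#'
#' @param m a `character_matrix`.
#' @param require_variable error if a character is invariant.
#' @return `m` invisibly; errors on violation.
#' @export
validate_character_matrix <- function(m, require_variable = FALSE) {
  nt <- length(m$taxa)
  if (length(m$cells) != m$nchar || length(m$state_count) != m$nchar ||
      length(m$ordered) != m$nchar || length(m$partition) != m$nchar)
    stop("inconsistent character_matrix dimensions")
  for (j in seq_len(m$nchar)) {
    col <- m$cells[[j]]
    if (length(col) != nt) stop("ragged matrix at character ", j)
    k <- m$state_count[j]
    for (i in seq_len(nt)) {
      s <- col[[i]]
      if (length(s) == 0L) stop("empty state set at taxon ", i, " character ", j)
      if (any(s < 0L | s >= k))
        stop("state outside 0..", k - 1L, " at taxon ", i, " character ", j)
    }
    if (require_variable && !is_variable_column(col))
      stop("character ", j, " is invariant")
  }
  invisible(m)
}

# a column is variable when >= 2 distinct singleton (fully observed) states occur
is_variable_column <- function(col) {
  obs <- unlist(col[lengths(col) == 1L])
  length(unique(obs)) >= 2L
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("character_matrix: %d taxa x %d characters (%d ordered), partitions: %s\n",
              length(x$taxa), x$nchar, sum(x$ordered),
              paste(unique(x$partition), collapse = ", ")))
  invisible(x)
}

# turn a raw NEXUS token ("0", "?", "-", "0/1", "(01)", "{01}") into a
# 0-based state set given state count k
.token_to_set <- function(tok, k) {
  if (tok %in% c("?", "-")) return(0:(k - 1L))
  tok <- gsub("[(){}/]", "", tok)
  sort(unique(as.integer(strsplit(tok, "")[[1]])))
}

#' Read a NEXUS morphological matrix
#'
#' Parses a standard-data NEXUS `DATA`/`CHARACTERS` block (digit symbols,
#' `?` missing, `-` gap, parenthesized or braced polymorphisms). Both `?`
#' and `-` expand to the full state set; polymorphic cells to the listed
#' set. Per-character state counts default to the maximum observed state
#' plus one, but never exceed the declared `SYMBOLS` range.
#'
#' @param path NEXUS file path.
#' @param ordered optional integer vector of 1-based indices of ordered
#'   characters.
#' @param partition optional named list of 1-based character index vectors
#'   (see [parse_index_ranges()]), one entry per partition.
#' @return a `character_matrix`.
#' @export
read_character_matrix <- function(path, ordered = NULL, partition = NULL) {
  raw <- ape::read.nexus.data(path)
  taxa <- names(raw)
  if (anyDuplicated(taxa)) stop("duplicate taxon names in NEXUS matrix")
  nc <- unique(lengths(raw))
  if (length(nc) != 1L) stop("ragged NEXUS matrix: unequal row lengths")
  txt <- toupper(paste(readLines(path, warn = FALSE), collapse = " "))
  sym <- regmatches(txt, regexpr("SYMBOLS\\s*=\\s*\"[^\"]*\"", txt))
  max_sym <- NA_integer_
  if (length(sym)) {
    digs <- as.integer(strsplit(gsub("[^0-9]", "", sym), "")[[1]])
    if (length(digs)) max_sym <- max(digs)
  }
  cells <- vector("list", nc)
  state_count <- integer(nc)
  for (j in seq_len(nc)) {
    toks <- vapply(raw, `[[`, character(1), j)
    obs <- suppressWarnings(as.integer(unlist(
      strsplit(gsub("[(){}/?-]", "", toks), ""))))
    obs <- obs[!is.na(obs)]
    if (!is.na(max_sym) && length(obs) && max(obs) > max_sym)
      stop("character ", j, " uses a state outside the declared SYMBOLS range")
    k <- max(2L, if (length(obs)) max(obs) + 1L else 2L)
    state_count[j] <- k
    cells[[j]] <- lapply(toks, .token_to_set, k = k)
  }
  ord <- rep(FALSE, nc)
  if (!is.null(ordered)) ord[ordered] <- TRUE
  m <- character_matrix(cells, taxa, state_count, ord)
  if (!is.null(partition)) m <- assign_partitions(m, partition)
  m
}

#' Write a character matrix to NEXUS
#'
#' Emits a standard `DATA` block with digit symbols; full-ambiguity cells
#' are written as `?`, partial polymorphisms as `(..)`.
#'
#' @param m a `character_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_character_matrix <- function(m, path) {
  kmax <- max(m$state_count)
  rows <- vapply(seq_along(m$taxa), function(i) {
    toks <- vapply(seq_len(m$nchar), function(j) {
      s <- m$cells[[j]][[i]]
      k <- m$state_count[j]
      if (length(s) == k) "?"
      else if (length(s) == 1L) as.character(s)
      else paste0("(", paste(s, collapse = ""), ")")
    }, character(1))
    paste0(m$taxa[i], "  ", paste(toks, collapse = ""))
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", length(m$taxa), m$nchar),
    sprintf("FORMAT DATATYPE=STANDARD SYMBOLS=\"%s\" MISSING=? GAP=-;",
            paste(0:(kmax - 1L), collapse = "")),
    "MATRIX", rows, ";", "END;"), con)
  invisible(path)
}

#' Summarize character composition
#'
#' Counts binary and multistate characters (by number of *observed*
#' distinct states, ignoring ambiguity expansions), ordered characters and
#' per-partition sizes.
#'
#' @param m a `character_matrix`.
#' @return a list with `n_char`, `n_taxa`, `n_binary`, `n_multistate`,
#'   `n_ordered`, and `partition_sizes` (named integer vector).
#' @export
classify_characters <- function(m) {
  nobs <- vapply(seq_len(m$nchar), function(j) {
    col <- m$cells[[j]]
    k <- m$state_count[j]
    obs <- unlist(col[lengths(col) < k])  # drop full-ambiguity cells
    length(unique(obs))
  }, integer(1))
  sizes <- table(factor(m$partition, levels = unique(m$partition)))
  list(n_char = m$nchar, n_taxa = length(m$taxa),
       n_binary = sum(nobs <= 2L), n_multistate = sum(nobs > 2L),
       n_ordered = sum(m$ordered),
       partition_sizes = stats::setNames(as.integer(sizes), names(sizes)))
}

#' Attach a partition scheme to a character matrix
#'
#' @param m a `character_matrix`.
#' @param scheme named list; each element a vector of 1-based character
#'   indices (or a range string such as `"1-53"`, see
#'   [parse_index_ranges()]). Every character must be covered exactly once.
#' @return `m` with partition labels set.
#' @export
assign_partitions <- function(m, scheme) {
  idx <- lapply(scheme, parse_index_ranges)
  all_idx <- unlist(idx)
  if (anyDuplicated(all_idx))
    stop("characters assigned to more than one partition: ",
         paste(unique(all_idx[duplicated(all_idx)]), collapse = ", "))
  if (!setequal(all_idx, seq_len(m$nchar)))
    stop("partition scheme must cover all ", m$nchar, " characters exactly once")
  lab <- character(m$nchar)
  for (nm in names(idx)) lab[idx[[nm]]] <- nm
  m$partition <- lab
  m
}

#' Parse 1-based index range specifications
#'
#' Accepts an integer vector (returned as-is) or a character vector of
#' tokens like `"5"`, `"1-53"`, `"1-9 12 20-25"` (NEXUS-style inclusive
#' ranges), returning the sorted vector of indices.
#'
#' @param x integer vector or character range specification.
#' @return integer vector of indices.
#' @export
parse_index_ranges <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  toks <- unlist(strsplit(paste(x, collapse = " "), "[ ,]+"))
  toks <- toks[nzchar(toks)]
  out <- lapply(toks, function(t) {
    if (grepl("-", t)) {
      ab <- as.integer(strsplit(t, "-")[[1]])
      ab[1]:ab[2]
    } else as.integer(t)
  })
  sort(unique(unlist(out)))
}

#' Read tip-age calibrations
#'
#' Reads a tab-separated table with columns `taxon`, `age_min`, `age_max`
#' (Ma). Rows with `age_min == age_max == 0` are extant. Each fossil age
#' receives a uniform prior over its stratigraphic range
#' `[age_min, age_max]`.
#'
#' @param path file path.
#' @param taxa optional vector of taxon labels that must all be calibrated.
#' @return a data.frame with columns `taxon`, `age_min`, `age_max`,
#'   `is_extant`.
#' @export
read_tip_calibrations <- function(path, taxa = NULL) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("taxon", "age_min", "age_max")
  if (!all(need %in% names(tab)))
    stop("calibration table needs columns: ", paste(need, collapse = ", "))
  tip_calibrations(tab$taxon, tab$age_min, tab$age_max, taxa = taxa)
}

#' Construct and validate tip calibrations
#'
#' @param taxon character vector of labels.
#' @param age_min,age_max numeric stratigraphic bounds in Ma.
#' @param taxa optional vector of taxon labels that must all be calibrated.
#' @return a data.frame with columns `taxon`, `age_min`, `age_max`,
#'   `is_extant`.
#' @export
tip_calibrations <- function(taxon, age_min, age_max, taxa = NULL) {
  if (any(age_min < 0)) stop("negative ages in calibrations")
  if (any(age_min > age_max)) stop("age_min > age_max in calibrations")
  if (anyDuplicated(taxon)) stop("duplicate taxa in calibrations")
  if (!is.null(taxa)) {
    miss <- setdiff(taxa, taxon)
    if (length(miss)) stop("taxa without calibration: ", paste(miss, collapse = ", "))
    extra <- setdiff(taxon, taxa)
    if (length(extra)) stop("calibrated taxa absent from matrix: ",
                            paste(extra, collapse = ", "))
  }
  data.frame(taxon = as.character(taxon), age_min = age_min, age_max = age_max,
             is_extant = age_min == 0 & age_max == 0,
             stringsAsFactors = FALSE)
}

#' Construct and validate a set of monophyly constraints
#'
#' Each named constraint is a set of taxon labels required to form a
#' monophyletic clade. Constraints must be proper subsets of the full
#' taxon set and pairwise nested or disjoint.
#'
#' @param clades named list of character vectors of taxon labels.
#' @param taxa full vector of taxon labels.
#' @return the validated named list, classed `constraint_set`.
#' @export
constraint_set <- function(clades, taxa) {
  for (nm in names(clades)) {
    cl <- clades[[nm]]
    if (!all(cl %in% taxa))
      stop("constraint ", nm, " names unknown taxa")
    if (length(cl) >= length(taxa))
      stop("constraint ", nm, " must be a proper subset of all taxa")
    if (length(cl) < 2L)
      stop("constraint ", nm, " needs at least two taxa")
  }
  nms <- names(clades)
  for (i in seq_along(clades)) for (j in seq_along(clades)) {
    if (i < j) {
      a <- clades[[i]]; b <- clades[[j]]
      inter <- intersect(a, b)
      if (length(inter) && !(all(a %in% b) || all(b %in% a)))
        stop("constraints ", nms[i], " and ", nms[j],
             " overlap without nesting")
    }
  }
  structure(clades, class = "constraint_set")
}

#' Read an analysis configuration file
#'
#' YAML file with optional top-level keys: `partitions` (named character
#' index ranges, 1-based inclusive), `ordered` (index ranges), and
#' `constraints` (named taxon lists).
#'
#' @param path YAML file path.
#' @return a list with elements `partitions`, `ordered`, `constraints`
#'   (each possibly `NULL`).
#' @export
read_analysis_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list(partitions = NULL, ordered = NULL, constraints = NULL)
  if (!is.null(cfg$partitions)) out$partitions <- cfg$partitions
  if (!is.null(cfg$ordered)) out$ordered <- parse_index_ranges(cfg$ordered)
  if (!is.null(cfg$constraints))
    out$constraints <- lapply(cfg$constraints, as.character)
  out
}
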