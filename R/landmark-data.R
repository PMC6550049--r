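#' Landmark dataset
#'
#' Container for a sample of 3D landmark configurations. Coordinates are
#' stored as a `K x 3 x n` array (landmarks x axes x specimens) in
#' millimetres, together with a group label per specimen. All specimens
#' share the same landmarks in the same canonical order; downstream
#' indexing is always by landmark label, never by raw position.
#'
#' @param coords numeric array `K x 3 x n` with dimnames
#'   `list(landmark_labels, c("x","y","z"), specimen_ids)`. A `K x 3`
#'   matrix is accepted for a single specimen.
#' @param groups character vector of group labels, one per specimen,
#'   either named by specimen id or in specimen order.
#'
#' @return An object of class `landmark_dataset` with elements `coords`,
#'   `groups` (named by specimen id) and `landmarks`.
#' @export
landmark_dataset <- function(coords, groups) {
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(nrow(coords), ncol(coords), 1L),
                    dimnames = c(dimnames(coords), list(NULL)))
  }
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[2] != 3L)
    stop("`coords` must be a K x 3 x n array of 3D landmark coordinates")
  K <- dim(coords)[1]
  n <- dim(coords)[3]
  if (K < 3L)
    stop("a landmark configuration needs at least 3 landmarks, got ", K)
  labels <- dimnames(coords)[[1]]
  if (is.null(labels)) labels <- sprintf("lm%02d", seq_len(K))
  if (anyDuplicated(labels))
    stop("duplicated landmark labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  ids <- dimnames(coords)[[3]]
  if (is.null(ids)) ids <- sprintf("spec%03d", seq_len(n))
  if (anyDuplicated(ids))
    stop("duplicated specimen ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (missing(groups) || is.null(groups)) groups <- rep("all", n)
  groups <- as.character(groups)
  if (!is.null(names(groups))) {
    missing_ids <- setdiff(ids, names(groups))
    if (length(missing_ids))
      stop("no group label for specimen(s): ",
           paste(missing_ids, collapse = ", "))
    groups <- groups[ids]
  } else {
    if (length(groups) == 1L) groups <- rep(groups, n)
    if (length(groups) != n)
      stop("`groups` must have one label per specimen")
    names(groups) <- ids
  }
  if (anyNA(groups)) stop("group labels must not be NA")
  storage.mode(coords) <- "double"
  bad <- which(!is.finite(coords), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-finite coordinate for specimen '", ids[bad[1, 3]],
         "', landmark '", labels[bad[1, 1]], "'")
  }
  dimnames(coords) <- list(labels, c("x", "y", "z"), ids)
  for (i in seq_len(n)) {
    d <- stats::dist(coords[, , i])
    if (any(d == 0)) {
      p <- pair_index(labels)[which(d == 0)[1], ]
      stop("coincident landmarks '", p$landmark_i, "' and '", p$landmark_j,
           "' in specimen '", ids[i], "'")
    }
  }
  structure(list(coords = coords, groups = groups, landmarks = labels),
            class = "landmark_dataset")
}

#' @export
print.landmark_dataset <- function(x, ...) {
  cat("<landmark_dataset>", n_specimens(x), "specimens x",
      n_landmarks(x), "landmarks\n")
  tab <- table(x$groups)
  cat("  groups:", paste(sprintf("%s (n=%d)", names(tab), tab),
                         collapse = ", "), "\n")
  cat("  landmarks:", paste(utils::head(x$landmarks, 8), collapse = " "),
      if (n_landmarks(x) > 8) "..." else "", "\n")
  invisible(x)
}

#' Dataset accessors
#'
#' @param dataset a `landmark_dataset`
#' @return `n_specimens()` / `n_landmarks()` counts, `specimen_ids()` /
#'   `landmark_labels()` character vectors, `specimen_groups()` the named
#'   group vector.
#' @export
n_specimens <- function(dataset) dim(dataset$coords)[3]

#' @rdname n_specimens
#' @export
n_landmarks <- function(dataset) dim(dataset$coords)[1]

#' @rdname n_specimens
#' @export
specimen_ids <- function(dataset) dimnames(dataset$coords)[[3]]

#' @rdname n_specimens
#' @export
landmark_labels <- function(dataset) dataset$landmarks

#' @rdname n_specimens
#' @export
specimen_groups <- function(dataset) dataset$groups

#' Canonical pair index
#'
#' All unique landmark pairs (i < j in label order), in the order used by
#' form matrices and distance tables: (1,2), (1,3), ..., (1,K), (2,3), ...
#' This matches the storage order of [stats::dist()].
#'
#' @param labels character vector of landmark labels
#' @return data.frame with columns `landmark_i`, `landmark_j`
#' @export
pair_index <- function(labels) {
  K <- length(labels)
  if (K < 2L) stop("need at least 2 labels")
  i <- rep(seq_len(K - 1L), times = (K - 1L):1L)
  j <- sequence((K - 1L):1L) + i
  data.frame(landmark_i = labels[i], landmark_j = labels[j],
             stringsAsFactors = FALSE)
}

.pair_names <- function(pairs) paste(pairs$landmark_i, pairs$landmark_j, sep = "|")

#' Select specimens of one group
#'
#' @param dataset a `landmark_dataset`
#' @param group group label to keep
#' @return `filter_group()` a `landmark_dataset` restricted to one group;
#'   `split_groups()` a named list of single-group datasets.
#' @export
filter_group <- function(dataset, group) {
  keep <- which(dataset$groups == group)
  if (!length(keep)) stop("no specimens in group '", group, "'")
  landmark_dataset(dataset$coords[, , keep, drop = FALSE],
                   dataset$groups[keep])
}

#' @rdname filter_group
#' @export
split_groups <- function(dataset) {
  gs <- unique(dataset$groups)
  stats::setNames(lapply(gs, function(g) filter_group(dataset, g)), gs)
}

# ---- file I/O -------------------------------------------------------------

.num_or_die <- function(x, what, df) {
  miss <- is.na(x) | trimws(x) == ""
  miss[is.na(miss)] <- TRUE
  if (any(miss))
    stop("missing ", what, " coordinate for specimen '",
         df$specimen[which(miss)[1]], "', landmark '",
         df$landmark[which(miss)[1]], "'")
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v))
    stop("non-numeric ", what, " coordinate '", x[which(is.na(v))[1]],
         "' for specimen '", df$specimen[which(is.na(v))[1]], "', landmark '",
         df$landmark[which(is.na(v))[1]], "'")
  v
}

#' Read a landmark coordinate table
#'
#' Reads 3D landmark coordinates from CSV. The long (tidy) dialect has
#' columns `specimen,group,landmark,x,y,z`, one row per landmark; the wide
#' dialect has one row per specimen with columns `specimen,group` followed
#' by `<label>_x,<label>_y,<label>_z` triples. Units are millimetres.
#' Landmark order is taken from the first specimen (long) or the column
#' order (wide) and enforced for all specimens; missing or non-numeric
#' coordinates are a hard error naming the specimen and landmark.
#'
#' @param path CSV file path
#' @param dialect `"long"` (default) or `"wide"`
#' @return a [landmark_dataset()]
#' @export
read_landmark_table <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  if (dialect == "long") .read_long(df) else .read_wide(df)
}

.read_long <- function(df) {
  need <- c("specimen", "group", "landmark", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("long dialect needs columns ", paste(need, collapse = ","),
         "; missing: ", paste(setdiff(need, names(df)), collapse = ","))
  if (nrow(df) == 0) stop("empty landmark table")
  if (anyDuplicated(df[c("specimen", "landmark")])) {
    d <- df[duplicated(df[c("specimen", "landmark")]), ]
    stop("duplicated entry for specimen '", d$specimen[1],
         "', landmark '", d$landmark[1], "'")
  }
  ids <- unique(df$specimen)
  labels <- df$landmark[df$specimen == ids[1]]
  for (s in ids) {
    have <- df$landmark[df$specimen == s]
    miss <- setdiff(labels, have)
    extra <- setdiff(have, labels)
    if (length(miss))
      stop("specimen '", s, "' lacks landmark '", miss[1], "'")
    if (length(extra))
      stop("specimen '", s, "' has landmark '", extra[1],
           "' absent from specimen '", ids[1], "'")
  }
  xyz <- cbind(.num_or_die(df$x, "x", df),
               .num_or_die(df$y, "y", df),
               .num_or_die(df$z, "z", df))
  K <- length(labels)
  coords <- array(NA_real_, c(K, 3, length(ids)),
                  dimnames = list(labels, c("x", "y", "z"), ids))
  groups <- character(length(ids))
  names(groups) <- ids
  for (si in seq_along(ids)) {
    rows <- df$specimen == ids[si]
    ord <- match(labels, df$landmark[rows])
    coords[, , si] <- xyz[rows, , drop = FALSE][ord, ]
    g <- unique(df$group[rows])
    if (length(g) != 1)
      stop("conflicting group labels for specimen '", ids[si], "'")
    groups[si] <- g
  }
  landmark_dataset(coords, groups)
}

.read_wide <- function(df) {
  if (!all(c("specimen", "group") %in% names(df)))
    stop("wide dialect needs columns specimen, group")
  if (nrow(df) == 0) stop("empty landmark table")
  cc <- setdiff(names(df), c("specimen", "group"))
  xs <- grep("_x$", cc, value = TRUE)
  labels <- sub("_x$", "", xs)
  for (lab in labels) {
    miss <- setdiff(paste0(lab, c("_x", "_y", "_z")), cc)
    if (length(miss)) stop("wide dialect: missing column ", miss[1])
  }
  stray <- setdiff(cc, paste0(rep(labels, each = 3), c("_x", "_y", "_z")))
  if (length(stray)) stop("wide dialect: unexpected column ", stray[1])
  if (anyDuplicated(df$specimen))
    stop("duplicated specimen id: ", df$specimen[duplicated(df$specimen)][1])
  K <- length(labels)
  ids <- df$specimen
  coords <- array(NA_real_, c(K, 3, length(ids)),
                  dimnames = list(labels, c("x", "y", "z"), ids))
  for (li in seq_along(labels)) {
    for (ai in 1:3) {
      col <- paste0(labels[li], "_", c("x", "y", "z")[ai])
      fake <- data.frame(specimen = ids, landmark = labels[li])
      coords[li, ai, ] <- .num_or_die(df[[col]], c("x", "y", "z")[ai], fake)
    }
  }
  landmark_dataset(coords, stats::setNames(df$group, ids))
}

#' Write a landmark coordinate table
#'
#' Inverse of [read_landmark_table()]; coordinates are written with 17
#' significant digits so that a read/write round trip is lossless to full
#' double precision.
#'
#' @param dataset a [landmark_dataset()]
#' @param path output CSV path
#' @param dialect `"long"` or `"wide"`
#' @export
write_landmark_table <- function(dataset, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  if (!inherits(dataset, "landmark_dataset")) stop("not a landmark_dataset")
  n <- n_specimens(dataset)
  if (n == 0) stop("refusing to write an empty dataset")
  ids <- specimen_ids(dataset)
  labels <- landmark_labels(dataset)
  fmt <- function(v) sprintf("%.17g", v)
  if (dialect == "long") {
    df <- data.frame(
      specimen = rep(ids, each = length(labels)),
      group = rep(dataset$groups, each = length(labels)),
      landmark = rep(labels, n),
      x = fmt(as.vector(dataset$coords[, 1, ])),
      y = fmt(as.vector(dataset$coords[, 2, ])),
      z = fmt(as.vector(dataset$coords[, 3, ])),
      stringsAsFactors = FALSE)
  } else {
    df <- data.frame(specimen = ids, group = unname(dataset$groups),
                     stringsAsFactors = FALSE)
    for (li in seq_along(labels)) {
      for (ai in 1:3) {
        df[[paste0(labels[li], "_", c("x", "y", "z")[ai])]] <-
          fmt(dataset$coords[li, ai, ])
      }
    }
  }
  ok <- try(utils::write.csv(df, path, row.names = FALSE, quote = TRUE),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("cannot write landmark table to ", path)
  invisible(path)
}

# ---- replicate digitization QC -------------------------------------------

#' Average two digitization trials with quality control
#'
#' Landmarks are typically digitized twice on each specimen and the two
#' trials averaged to minimize observer error. This returns the per-axis
#' arithmetic mean of the two trials together with a QC report of the
#' Euclidean inter-trial displacement of every landmark. Landmarks whose
#' displacement exceeds `max_error` (default 0.05 mm) are flagged but still
#' averaged: flagging is advisory, and re-digitization or exclusion is left
#' to the user.
#'
#' @param trial_a,trial_b `landmark_dataset` objects with identical
#'   specimen ids and landmark labels (any order)
#' @param max_error advisory placement-error threshold in mm
#' @return list with `dataset` (the averaged `landmark_dataset`) and `qc`
#'   (a `trial_qc` report: per-landmark displacements, `max_displacement`,
#'   and the flagged (specimen, landmark) pairs)
#' @export
average_digitization_trials <- function(trial_a, trial_b, max_error = 0.05) {
  ids <- specimen_ids(trial_a)
  labels <- landmark_labels(trial_a)
  if (!setequal(ids, specimen_ids(trial_b)))
    stop("trials have different specimen sets")
  if (!setequal(labels, landmark_labels(trial_b)))
    stop("trials have different landmark sets")
  b <- trial_b$coords[labels, , ids, drop = FALSE]
  a <- trial_a$coords
  avg <- (a + b) / 2
  disp <- sqrt(apply((a - b)^2, c(1, 3), sum))  # K x n
  rep_df <- data.frame(
    specimen = rep(ids, each = length(labels)),
    landmark = rep(labels, length(ids)),
    displacement = as.vector(disp),
    stringsAsFactors = FALSE)
  flagged <- rep_df[rep_df$displacement > max_error, , drop = FALSE]
  rownames(flagged) <- NULL
  qc <- structure(list(displacements = rep_df,
                       max_displacement = max(rep_df$displacement),
                       threshold = max_error,
                       flagged = flagged),
                  class = "trial_qc")
  list(dataset = landmark_dataset(avg, trial_a$groups), qc = qc)
}

#' @export
print.trial_qc <- function(x, ...) {
  cat("<trial_qc> inter-trial landmark displacement\n")
  cat(sprintf("  max displacement: %.4f mm (threshold %.3f mm)\n",
              x$max_displacement, x$threshold))
  cat("  flagged:", nrow(x$flagged), "of", nrow(x$displacements),
      "landmark placements\n")
  invisible(x)
}

# ---- subsets and bilateral matching --------------------------------------

#' Named landmark subset
#'
#' @param name subset name (e.g. "ramus")
#' @param labels character vector of at least 3 landmark labels
#' @return a `subset_definition`
#' @export
subset_definition <- function(name, labels) {
  labels <- as.character(labels)
  if (length(labels) < 3L)
    stop("subset '", name, "' has fewer than 3 landmarks")
  if (anyDuplicated(labels))
    stop("subset '", name, "' repeats label '",
         labels[duplicated(labels)][1], "'")
  structure(list(name = name, labels = labels), class = "subset_definition")
}

#' Read subset definitions from YAML or CSV
#'
#' YAML: a mapping `name: [label, ...]`. CSV: columns `name,label`, one
#' row per (subset, landmark).
#'
#' @param path file path (.yaml/.yml or .csv)
#' @return named list of [subset_definition()] objects
#' @export
read_subset_definitions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    raw <- yaml::read_yaml(path)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("name", "label") %in% names(df)))
      stop("subset CSV needs columns name,label")
    raw <- split(df$label, df$name)
  }
  stats::setNames(
    lapply(names(raw), function(nm) subset_definition(nm, raw[[nm]])),
    names(raw))
}

#' Extract a landmark subset
#'
#' Restricts a dataset to a named subset of its landmarks (e.g. the ramus
#' or anterior-body landmarks of a hemimandible), reordering them to the
#' subset order. Group labels are unchanged.
#'
#' @param dataset a [landmark_dataset()]
#' @param subset a [subset_definition()] or character vector of labels
#' @return a [landmark_dataset()] with only the subset landmarks
#' @export
extract_subset <- function(dataset, subset) {
  labels <- if (inherits(subset, "subset_definition")) subset$labels
            else as.character(subset)
  if (length(labels) < 3L)
    stop("subset has fewer than 3 landmarks")
  unknown <- setdiff(labels, landmark_labels(dataset))
  if (length(unknown))
    stop("unknown landmark label '", unknown[1], "'")
  landmark_dataset(dataset$coords[labels, , , drop = FALSE], dataset$groups)
}

#' Match bilateral landmarks for asymmetry analysis
#'
#' Splits a dataset into left- and right-side datasets using a one-to-one
#' pairing of homologous landmark labels, relabeling the right-side
#' landmarks to their left homologs in matching order. Because inter-
#' landmark distances are invariant to reflection, the two returned
#' datasets can be compared directly by EDMA (mirror-symmetric anatomy
#' gives identical form matrices).
#'
#' @param dataset a [landmark_dataset()]
#' @param pairing data.frame with columns `left`, `right` (or 2-column
#'   matrix), one row per homologous landmark pair
#' @return list with elements `left` and `right`, both `landmark_dataset`s
#'   carrying the left-side labels
#' @export
match_bilateral <- function(dataset, pairing) {
  pairing <- as.data.frame(pairing, stringsAsFactors = FALSE)
  if (ncol(pairing) == 2 && !all(c("left", "right") %in% names(pairing)))
    names(pairing) <- c("left", "right")
  if (!all(c("left", "right") %in% names(pairing)))
    stop("pairing needs columns left, right")
  left <- as.character(pairing$left)
  right <- as.character(pairing$right)
  if (anyDuplicated(left) || anyDuplicated(right) ||
      length(intersect(left, right)))
    stop("bilateral pairing must be one-to-one with disjoint sides")
  unknown <- setdiff(c(left, right), landmark_labels(dataset))
  if (length(unknown))
    stop("pairing label '", unknown[1], "' not in dataset")
  lds <- extract_subset(dataset, left)
  rc <- dataset$coords[right, , , drop = FALSE]
  dimnames(rc)[[1]] <- left
  list(left = lds, right = landmark_dataset(rc, dataset$groups))
}

#' Read a bilateral pairing from CSV or YAML
#'
#' CSV: columns `left,right`. YAML: a mapping `left_label: right_label`.
#'
#' @param path file path
#' @return data.frame with columns `left`, `right`
#' @export
read_bilateral_pairing <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    raw <- yaml::read_yaml(path)
    data.frame(left = names(raw), right = unlist(raw, use.names = FALSE),
               stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("left", "right") %in% names(df)))
      stop("pairing CSV needs columns left,right")
    df[c("left", "right")]
  }
}
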