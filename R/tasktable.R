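# MoleculeNet-style multi-task tables and task splits.
#
# On disk a task table is a plain CSV with a header row, one column named
# "smiles" and one column per task; cells are "1", "0" or empty (empty =
# unlabeled for that task). A task split is a JSON file with arrays
# "train_tasks" and "test_tasks".

#' Construct a multi-task label table
#'
#' @param smiles Character vector of SMILES strings.
#' @param labels Data frame (or matrix) of task labels, one column per task;
#'   entries must be 0, 1 or NA (NA = unlabeled).
#' @return A `task_table`: list with `smiles` (character), `labels` (integer
#'   data frame with NA for missing) and `task_names`.
#' @export
task_table <- function(smiles, labels) {
  labels <- as.data.frame(labels)
  if (length(smiles) != nrow(labels)) {
    stop("task_table(): 'smiles' and 'labels' row counts differ")
  }
  if (ncol(labels) == 0L) stop("task_table(): at least one task column required")
  if (anyDuplicated(names(labels))) stop("task_table(): duplicate task names")
  for (nm in names(labels)) {
    v <- labels[[nm]]
    if (!all(is.na(v) | v %in% c(0, 1))) {
      stop(sprintf("task_table(): task '%s' has labels outside {0, 1, NA}", nm))
    }
    labels[[nm]] <- as.integer(v)
  }
  all_missing <- rowSums(!is.na(labels)) == 0L
  if (any(all_missing)) {
    stop(sprintf("task_table(): %d record(s) have no label for any task",
                 sum(all_missing)))
  }
  structure(list(smiles = as.character(smiles), labels = labels,
                 task_names = names(labels)),
            class = "task_table")
}

#' @export
print.task_table <- function(x, ...) {
  cat(sprintf("<task_table> %d molecules x %d tasks\n",
              length(x$smiles), length(x$task_names)))
  for (nm in x$task_names) {
    v <- x$labels[[nm]]
    cat(sprintf("  %s: %d labelled (%d pos / %d neg)\n", nm,
                sum(!is.na(v)), sum(v == 1L, na.rm = TRUE),
                sum(v == 0L, na.rm = TRUE)))
  }
  invisible(x)
}

#' Read a multi-task label table from CSV
#'
#' Missing cells are preserved as `NA`, never imputed to 0; row order is
#' preserved. Any label token other than `1`, `0` or the empty string is an
#' error rather than being coerced.
#'
#' @param path Path to a comma-delimited file with a header row, a column
#'   named `smiles`, and one column per task.
#' @return A [task_table()].
#' @export
read_task_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("task table '%s' does not exist", path))
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = NULL)
  if (nrow(df) == 0L) stop(sprintf("task table '%s' is empty", path))
  if (!"smiles" %in% names(df)) {
    stop(sprintf("task table '%s' has no 'smiles' column", path))
  }
  task_cols <- setdiff(names(df), "smiles")
  if (length(task_cols) == 0L) {
    stop(sprintf("task table '%s' has no task columns", path))
  }
  labels <- lapply(task_cols, function(nm) {
    v <- trimws(df[[nm]])
    bad <- !(v %in% c("0", "1", ""))
    if (any(bad)) {
      stop(sprintf(
        "task table '%s', task '%s': unparseable label '%s' in row %d (expected 1, 0 or empty)",
        path, nm, v[which(bad)[1]], which(bad)[1]))
    }
    ifelse(v == "", NA_integer_, as.integer(v))
  })
  names(labels) <- task_cols
  task_table(df$smiles, as.data.frame(labels, check.names = FALSE))
}

#' Write a multi-task label table to CSV
#'
#' Inverse of [read_task_table()]: missing labels become empty cells.
#'
#' @param table A [task_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_task_table <- function(table, path) {
  stopifnot(inherits(table, "task_table"))
  out <- data.frame(smiles = table$smiles, check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (nm in table$task_names) {
    v <- table$labels[[nm]]
    out[[nm]] <- ifelse(is.na(v), "", as.character(v))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a meta-train / meta-test task split
#'
#' @param train_tasks,test_tasks Character vectors of task names; must be
#'   disjoint.
#' @return A `task_split` object.
#' @export
task_split <- function(train_tasks, test_tasks) {
  train_tasks <- as.character(train_tasks)
  test_tasks <- as.character(test_tasks)
  if (length(intersect(train_tasks, test_tasks)) > 0L) {
    stop("task_split(): train and test tasks overlap")
  }
  structure(list(train_tasks = train_tasks, test_tasks = test_tasks),
            class = "task_split")
}

#' @export
print.task_split <- function(x, ...) {
  cat(sprintf("<task_split> %d train / %d test task(s)\n  train: %s\n  test:  %s\n",
              length(x$train_tasks), length(x$test_tasks),
              paste(x$train_tasks, collapse = ", "),
              paste(x$test_tasks, collapse = ", ")))
  invisible(x)
}

#' Read a task split from JSON
#'
#' @param path JSON file with string arrays `train_tasks` and `test_tasks`.
#' @param table Optional [task_table()]; when given, split membership is
#'   checked against its task names.
#' @return A [task_split()].
#' @export
read_task_split <- function(path, table = NULL) {
  if (!file.exists(path)) stop(sprintf("task split '%s' does not exist", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("train_tasks", "test_tasks") %in% names(obj))) {
    stop(sprintf("task split '%s' must have keys 'train_tasks' and 'test_tasks'",
                 path))
  }
  sp <- task_split(obj$train_tasks, obj$test_tasks)
  if (!is.null(table)) validate_split(sp, table)
  sp
}

#' Write a task split to JSON
#'
#' @param split A [task_split()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_task_split <- function(split, path) {
  stopifnot(inherits(split, "task_split"))
  jsonlite::write_json(list(train_tasks = split$train_tasks,
                            test_tasks = split$test_tasks),
                       path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

validate_split <- function(split, table) {
  unknown <- setdiff(c(split$train_tasks, split$test_tasks), table$task_names)
  if (length(unknown) > 0L) {
    stop(sprintf("task split names unknown to the table: %s",
                 paste(unknown, collapse = ", ")))
  }
  invisible(split)
}

#' Materialize the labelled dataset of one task
#'
#' Parses every molecule with a non-missing label for `task` and returns the
#' graph/label pairs; records unlabeled for this task are excluded.
#'
#' @param table A [task_table()].
#' @param task A task name present in `table$task_names`.
#' @return A `task_dataset`: list with `graphs` (list of [parse_smiles()]
#'   graphs), `labels` (integer 0/1 vector), `task` and class counts
#'   `n_pos` / `n_neg`.
#' @export
task_dataset <- function(table, task) {
  stopifnot(inherits(table, "task_table"))
  if (!task %in% table$task_names) {
    stop(sprintf("unknown task '%s' (available: %s)", task,
                 paste(table$task_names, collapse = ", ")))
  }
  keep <- which(!is.na(table$labels[[task]]))
  labels <- table$labels[[task]][keep]
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop(sprintf(
      "task '%s' has %d positive and %d negative labelled molecules; both classes are required to form episodes",
      task, n_pos, n_neg))
  }
  graphs <- lapply(table$smiles[keep], parse_smiles)
  structure(list(graphs = graphs, labels = labels, task = task,
                 n_pos = n_pos, n_neg = n_neg),
            class = "task_dataset")
}

#' @export
print.task_dataset <- function(x, ...) {
  cat(sprintf("<task_dataset> '%s': %d molecules (%d pos / %d neg)\n",
              x$task, length(x$labels), x$n_pos, x$n_neg))
  invisible(x)
}
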