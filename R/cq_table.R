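#' Construct a table of qPCR quantification-cycle measurements
#'
#' A `cq_table` holds long-format real-time qPCR data: one row per technical
#' replicate of one gene in one sample, with the sample's experimental group
#' and, optionally, the gene's amplification efficiency E (the per-cycle
#' template amplification factor; 2 means perfect doubling).
#'
#' @param records data.frame with columns `sample_id`, `group`, `gene`,
#'   `replicate` (integer >= 1) and `cq` (finite, > 0); an `efficiency`
#'   column (per gene, 1 < E <= 2) is optional. Extra columns are kept as
#'   metadata.
#' @param experiment_id single string naming the experiment.
#'
#' @return An object of class `cq_table`: the validated data.frame with an
#'   `experiment_id` attribute.
#' @export
#' @examples
#' df <- data.frame(sample_id = "S1", group = "red", gene = "CYB5",
#'                  replicate = 1:2, cq = c(30.1, 30.3))
#' cq_table(df, experiment_id = "demo")
cq_table <- function(records, experiment_id = "experiment") {
  required <- c("sample_id", "group", "gene", "replicate", "cq")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop_rgstab(
      sprintf("missing required column(s): %s",
              paste(missing_cols, collapse = ", ")),
      "rgstab_format_error"
    )
  }
  records$sample_id <- as.character(records$sample_id)
  records$group     <- as.character(records$group)
  records$gene      <- as.character(records$gene)

  if (!is.numeric(records$cq)) {
    bad <- which(is.na(suppressWarnings(as.numeric(records$cq))))
    stop_rgstab(
      sprintf("non-numeric Cq value(s) at row(s): %s",
              paste(utils::head(bad, 5), collapse = ", ")),
      "rgstab_parse_error"
    )
  }
  if (any(!is.finite(records$cq)) || any(records$cq <= 0)) {
    bad <- which(!is.finite(records$cq) | records$cq <= 0)
    stop_rgstab(
      sprintf("Cq must be finite and > 0; offending row(s): %s",
              paste(utils::head(bad, 5), collapse = ", ")),
      "rgstab_parse_error"
    )
  }
  records$replicate <- as.integer(records$replicate)
  if (any(is.na(records$replicate)) || any(records$replicate < 1L)) {
    stop_rgstab("replicate must be an integer >= 1", "rgstab_parse_error")
  }

  key <- paste(records$sample_id, records$gene, records$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- records[duplicated(key), , drop = FALSE]
    stop_rgstab(
      sprintf("duplicated (sample, gene, replicate) triple(s), e.g. (%s, %s, %d)",
              dup$sample_id[1], dup$gene[1], dup$replicate[1]),
      "rgstab_integrity_error"
    )
  }

  grp_per_sample <- tapply(records$group, records$sample_id,
                           function(g) length(unique(g)))
  if (any(grp_per_sample > 1L)) {
    offender <- names(grp_per_sample)[grp_per_sample > 1L][1]
    stop_rgstab(
      sprintf("sample '%s' is assigned to more than one group", offender),
      "rgstab_integrity_error"
    )
  }

  if ("efficiency" %in% names(records)) {
    e <- records$efficiency
    if (any(!is.na(e) & (e <= 1 | e > 2))) {
      bad_gene <- records$gene[which(!is.na(e) & (e <= 1 | e > 2))][1]
      stop_rgstab(
        sprintf("efficiency for gene '%s' outside (1, 2]", bad_gene),
        "rgstab_domain_error"
      )
    }
    e_per_gene <- tapply(e, records$gene, function(x) length(unique(x[!is.na(x)])))
    if (any(e_per_gene > 1L)) {
      offender <- names(e_per_gene)[e_per_gene > 1L][1]
      stop_rgstab(
        sprintf("gene '%s' has more than one efficiency value", offender),
        "rgstab_integrity_error"
      )
    }
  }

  structure(as.data.frame(records),
            experiment_id = as.character(experiment_id),
            class = c("cq_table", "data.frame"))
}

#' Read a Cq table from delimited text
#'
#' Expects a header with columns `sample_id`, `group`, `gene`, `replicate`,
#' `cq`; an `efficiency` column is optional and unknown columns are kept.
#'
#' @param path file path.
#' @param sep field separator; `","` (default) or `"\t"`.
#' @param experiment_id experiment label stored on the result.
#' @return A [cq_table].
#' @export
read_cq_table <- function(path, sep = ",", experiment_id = NULL) {
  if (!file.exists(path)) {
    stop_rgstab(sprintf("file not found: %s", path), "rgstab_io_error")
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  cq_table(df, experiment_id = experiment_id %||%
             sub("\\.[^.]*$", "", basename(path)))
}

#' Write a Cq table to delimited text
#' @param table a [cq_table].
#' @param path output file.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_cq_table <- function(table, path, sep = ",") {
  stopifnot(inherits(table, "cq_table"))
  utils::write.table(as.data.frame(table), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.cq_table <- function(x, ...) {
  cat(sprintf("<cq_table> experiment '%s': %d records, %d genes, %d samples\n",
              attr(x, "experiment_id"), nrow(x),
              length(unique(x$gene)), length(unique(x$sample_id))))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

# Per-gene efficiency map (named numeric) from a cq_table, or NULL when the
# column is absent / all NA.
cq_efficiencies <- function(table) {
  if (!"efficiency" %in% names(table)) return(NULL)
  e <- tapply(table$efficiency, table$gene,
              function(x) if (all(is.na(x))) NA_real_ else x[!is.na(x)][1])
  if (all(is.na(e))) return(NULL)
  e <- e[!is.na(e)]
  stats::setNames(as.numeric(e), names(e))
}

# sample -> group map (named character) from a cq_table.
cq_groups <- function(table) {
  first <- !duplicated(table$sample_id)
  stats::setNames(table$group[first], table$sample_id[first])
}
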