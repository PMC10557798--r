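read_table_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read and validate a gRNA-target alignment table
#'
#' Reads a CSV/TSV table, validates each row against the declared schema,
#' and attaches encodings. Schemas: \code{"invitro"} needs columns
#' \code{guide}, \code{pam}, \code{target_alignment} and a strictly
#' positive \code{rate}; \code{"invivo"} needs the same sequence columns
#' and a 0/1 \code{label}; \code{"pairing"} needs \code{guide_seq},
#' \code{target_seq} and a positive \code{cleavage_rate} (the simulator's
#' output shape). Malformed rows are collected into an error report (and
#' dropped), or abort immediately with \code{fail_fast = TRUE}.
#'
#' @param path file path.
#' @param schema one of \code{"invitro"}, \code{"invivo"}, \code{"pairing"}.
#' @param encode attach the encoding array (25 x 13 for alignment schemas,
#'   L x 4 for pairing).
#' @param L pairing-encoding length.
#' @param fail_fast stop at the first malformed row.
#' @return list of class \code{"alignment_dataset"}: \code{table} (valid
#'   rows), \code{X} (encoding array or NULL), \code{errors} (data.frame
#'   row/message).
#' @export
read_alignment_table <- function(path, schema = c("invitro", "invivo", "pairing"),
                                 encode = TRUE, L = 50L, fail_fast = FALSE) {
  schema <- match.arg(schema)
  tab <- read_table_auto(path)
  need <- switch(schema,
                 invitro = c("guide", "pam", "target_alignment", "rate"),
                 invivo  = c("guide", "pam", "target_alignment", "label"),
                 pairing = c("guide_seq", "target_seq", "cleavage_rate"))
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  errs <- list()
  bad_row <- function(i, msg) {
    if (fail_fast) stop("row ", i, ": ", msg)
    errs[[length(errs) + 1L]] <<- data.frame(row = i, message = msg,
                                             stringsAsFactors = FALSE)
  }
  n <- nrow(tab)
  keep <- rep(TRUE, n)
  encs <- vector("list", n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      if (schema == "pairing") {
        lab <- suppressWarnings(as.numeric(tab$cleavage_rate[i]))
        if (!is.finite(lab) || lab <= 0)
          stop("cleavage_rate must be a positive number")
        if (encode) encode_pairing(tab$guide_seq[i], tab$target_seq[i], L)
        else TRUE
      } else {
        lab <- suppressWarnings(as.numeric(tab[[need[4L]]][i]))
        if (schema == "invitro" && (!is.finite(lab) || lab <= 0))
          stop("rate must be a positive number")
        if (schema == "invivo" && (!lab %in% c(0, 1)))
          stop("label must be 0 or 1")
        encode_invivo(tab$guide[i], tab$pam[i], tab$target_alignment[i])
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      bad_row(i, conditionMessage(res))
      keep[i] <- FALSE
    } else if (encode) encs[[i]] <- res
  }
  X <- NULL
  if (encode && any(keep)) {
    d <- dim(encs[[which(keep)[1L]]])
    X <- array(0, c(sum(keep), d))
    for (j in seq_along(which(keep))) X[j, , ] <- encs[[which(keep)[j]]]
  }
  structure(list(table = tab[keep, , drop = FALSE], X = X,
                 errors = if (length(errs)) do.call(rbind, errs)
                          else data.frame(row = integer(), message = character())),
            class = "alignment_dataset")
}

#' Split a dataset by guide sequence
#'
#' Holds out a fraction of the distinct guides -- and every record of those
#' guides -- so that no guide leaks between partitions; the fraction
#' applies to guides, not rows.
#'
#' @param guides character/integer vector of per-record guide identifiers,
#'   or a data.frame with a \code{guide} column.
#' @param holdout_fraction fraction of guides to hold out.
#' @param seed integer seed.
#' @return list with integer index vectors \code{train} and
#'   \code{validation}.
#' @export
split_by_guide <- function(guides, holdout_fraction = 0.2, seed = 1L) {
  if (is.data.frame(guides)) guides <- guides$guide
  gu <- unique(guides)
  if (length(gu) < 2L)
    stop("need at least 2 distinct guides to split")
  set.seed(seed)
  n_hold <- max(1L, round(holdout_fraction * length(gu)))
  if (n_hold >= length(gu)) n_hold <- length(gu) - 1L
  hold <- sample(gu, n_hold)
  val <- which(guides %in% hold)
  list(train = setdiff(seq_along(guides), val), validation = val)
}

# ---- JSON (de)serialization -------------------------------------------------

#' Read or write a kinetic scheme as JSON
#'
#' Format: \code{\{"n_states": int, "edges": [\{"from", "to", "symbol"\}...],
#' "activity_edges": [...], "reservoir_concentration": x,
#' "binding_edge": "k01"\}}, states 0-indexed.
#'
#' @param scheme a \code{\link{kinetic_scheme}}.
#' @param path file path.
#' @return \code{read_scheme_json} returns a \code{kinetic_scheme};
#'   \code{write_scheme_json} returns \code{path} invisibly.
#' @export
write_scheme_json <- function(scheme, path) {
  obj <- list(n_states = scheme$n_states,
              edges = scheme$edges,
              activity_edges = scheme$activity_edges,
              reservoir_concentration = scheme$reservoir_concentration,
              binding_edge = scheme$binding_edge)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_scheme_json
#' @export
read_scheme_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  kinetic_scheme(obj$n_states, obj$edges[, c("from", "to")],
                 activity_edges = unlist(obj$activity_edges),
                 reservoir_concentration = obj$reservoir_concentration %||% 1,
                 binding_edge = obj$binding_edge)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a rate assignment from JSON or CSV
#'
#' Accepts a flat JSON map \code{\{"k01": value, ...\}} or a CSV/TSV with
#' columns \code{symbol}, \code{value}.
#'
#' @param path file path.
#' @return named numeric rate vector.
#' @export
read_rates <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(unlist(obj))
  }
  tab <- read_table_auto(path)
  stats::setNames(as.numeric(tab$value), tab$symbol)
}

enc_arrays <- function(p) {
  if (is.list(p)) return(lapply(p, enc_arrays))
  list(dim = if (is.matrix(p)) dim(p) else length(p), data = as.numeric(p))
}

dec_arrays <- function(p) {
  if (is.list(p) && !is.null(p$data) && !is.null(p$dim)) {
    d <- unlist(p$dim); v <- as.numeric(unlist(p$data))
    return(if (length(d) == 2L) matrix(v, d[1L], d[2L]) else v)
  }
  lapply(p, dec_arrays)
}

#' Save or load a KINN checkpoint as JSON
#'
#' Checkpoints carry the architecture block (scheme, windows, head, link)
#' and named parameter arrays with shapes; no code objects, so a checkpoint
#' is loadable anywhere.
#'
#' @param model a \code{kinn_model} (or list with \code{architecture},
#'   \code{parameters}).
#' @param path file path.
#' @return \code{load_kinn} returns a \code{kinn_model}-shaped list.
#' @export
save_kinn <- function(model, path) {
  arch <- model$architecture
  obj <- list(scheme = list(n_states = arch$scheme$n_states,
                            edges = arch$scheme$edges,
                            activity_edges = arch$scheme$activity_edges,
                            reservoir_concentration = arch$scheme$reservoir_concentration,
                            binding_edge = arch$scheme$binding_edge),
              windows = arch$windows,
              input_length = arch$input_length,
              channels = arch$channels,
              output_head = arch$output_head,
              link = arch$link,
              parameters = enc_arrays(unclass(model$parameters)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_kinn
#' @export
load_kinn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  scheme <- kinetic_scheme(obj$scheme$n_states,
                           obj$scheme$edges[, c("from", "to")],
                           activity_edges = unlist(obj$scheme$activity_edges),
                           reservoir_concentration = obj$scheme$reservoir_concentration %||% 1,
                           binding_edge = obj$scheme$binding_edge)
  link <- kinn_link(hidden = obj$link$hidden, act_nu = obj$link$act_nu,
                    act_o = obj$link$act_o, trainable = obj$link$trainable)
  arch <- kinn_architecture(scheme, obj$windows, obj$input_length,
                            obj$channels, output_head = obj$output_head,
                            link = link)
  params <- dec_arrays(obj$parameters)
  class(params) <- "kinn_parameters"
  structure(list(architecture = arch, parameters = params),
            class = "kinn_model")
}

#' Save or load a transfer-model checkpoint as JSON
#'
#' Embeds the backbone spec, all trainable parameter arrays, the frozen
#' KINN checkpoint, and the frozen-parameter fingerprint (verified on
#' load).
#'
#' @param model a trained \code{\link{transfer_model}}.
#' @param path file path.
#' @return \code{load_transfer} returns a \code{transfer_model}.
#' @export
save_transfer <- function(model, path) {
  kin_tmp <- tempfile(fileext = ".json")
  save_kinn(model$frozen, kin_tmp)
  obj <- list(spec = model$spec,
              params = enc_arrays(model$params),
              frozen = jsonlite::read_json(kin_tmp, simplifyVector = TRUE),
              frozen_fingerprint = model$frozen_fingerprint)
  unlink(kin_tmp)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_transfer
#' @export
load_transfer <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  kin_tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(obj$frozen, kin_tmp, auto_unbox = TRUE, digits = I(17))
  frozen <- load_kinn(kin_tmp)
  unlink(kin_tmp)
  sp <- backbone_spec(conv1 = obj$spec$conv1, conv2 = obj$spec$conv2,
                      dropout = obj$spec$dropout,
                      recurrent = obj$spec$recurrent,
                      flatten = obj$spec$flatten,
                      filters = obj$spec$filters)
  model <- transfer_model(frozen, sp, seed = 1L)
  model$params <- dec_arrays(obj$params)
  if (!identical(param_fingerprint(frozen$parameters),
                 obj$frozen_fingerprint))
    stop("frozen KINN fingerprint mismatch in checkpoint")
  model
}

#' Write a reproducibility manifest for a run
#'
#' @param out_dir output directory.
#' @param config named list of run parameters (subcommand, seed, inputs).
#' @param outputs character vector of produced files.
#' @return the manifest path, invisibly.
#' @export
write_manifest <- function(out_dir, config, outputs = character()) {
  man <- list(config = config,
              outputs = as.list(outputs),
              package_version = as.character(utils::packageVersion("kinn")),
              r_version = R.version.string,
              timestamp = format(Sys.time(), tz = "UTC"))
  path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}
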