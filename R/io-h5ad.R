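# Minimal AnnData (.h5ad) writer/reader over rhdf5.
#
# Implements the AnnData on-disk encodings needed here: csc_matrix groups for
# sparse cells x genes matrices, C-order dense arrays (R matrices are
# transposed on write so Python readers see (n_obs, n_var)), dataframe groups
# for obs/var, and dict groups for layers/obsm/uns.

# attribute writes are queued and applied after all datasets exist, so the
# name-based dataset writes never race an open file handle
h5_attr_queue <- function() {
  q <- new.env(parent = emptyenv())
  q$items <- list()
  q
}

h5_set_attr <- function(fid, objname, name, value) {
  fid$items[[length(fid$items) + 1L]] <- list(obj = objname, name = name, value = value)
}

h5_apply_attrs <- function(path, queue) {
  fid <- rhdf5::H5Fopen(path)
  on.exit({rhdf5::H5Fclose(fid); rhdf5::h5closeAll()}, add = TRUE)
  for (it in queue$items) {
    obj <- rhdf5::H5Oopen(fid, it$obj)
    if (is.character(it$value)) {
      rhdf5::h5writeAttribute(it$value, obj, it$name, variableLengthString = TRUE,
                              asScalar = length(it$value) == 1, encoding = "UTF-8")
    } else {
      rhdf5::h5writeAttribute(it$value, obj, it$name, asScalar = length(it$value) == 1)
    }
    rhdf5::H5Oclose(obj)
  }
}

h5_mark <- function(fid, objname, type, version) {
  h5_set_attr(fid, objname, "encoding-type", type)
  h5_set_attr(fid, objname, "encoding-version", version)
}

h5_write_array <- function(path, fid, name, v) {
  if (is.logical(v)) v <- as.integer(v)
  if (is.matrix(v)) {
    rhdf5::h5write(t(v), path, name)      # file dims (nrow, ncol) in C order
    h5_mark(fid, name, "array", "0.2.0")
  } else if (is.character(v)) {
    rhdf5::h5write(v, path, name, variableLengthString = TRUE, encoding = "UTF-8")
    h5_mark(fid, name, "string-array", "0.2.0")
  } else {
    rhdf5::h5write(v, path, name)
    h5_mark(fid, name, "array", "0.2.0")
  }
}

h5_write_X <- function(path, fid, name, m) {
  if (inherits(m, "sparseMatrix")) {
    m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
    rhdf5::h5createGroup(path, name)
    rhdf5::h5write(m@x, path, paste0(name, "/data"))
    rhdf5::h5write(m@i, path, paste0(name, "/indices"))
    rhdf5::h5write(m@p, path, paste0(name, "/indptr"))
    h5_mark(fid, name, "csc_matrix", "0.1.0")
    h5_set_attr(fid, name, "shape", dim(m))
  } else {
    h5_write_array(path, fid, name, as.matrix(m))
  }
}

h5_write_df <- function(path, fid, name, df) {
  rhdf5::h5createGroup(path, name)
  idx <- rownames(df) %||% as.character(seq_len(nrow(df)))
  rhdf5::h5write(idx, path, paste0(name, "/_index"),
                 variableLengthString = TRUE, encoding = "UTF-8")
  h5_mark(fid, paste0(name, "/_index"), "string-array", "0.2.0")
  for (col in names(df)) {
    v <- df[[col]]
    if (is.factor(v)) v <- as.character(v)
    h5_write_array(path, fid, paste0(name, "/", col), v)
  }
  h5_mark(fid, name, "dataframe", "0.2.0")
  h5_set_attr(fid, name, "_index", "_index")
  h5_set_attr(fid, name, "column-order",
              if (length(names(df))) names(df) else numeric(0))
}

h5_write_dict <- function(path, fid, name, lst, as_matrix = FALSE) {
  rhdf5::h5createGroup(path, name)
  h5_mark(fid, name, "dict", "0.1.0")
  for (key in names(lst)) {
    el <- lst[[key]]
    full <- paste0(name, "/", key)
    if (as_matrix || is.matrix(el) || inherits(el, "sparseMatrix")) {
      h5_write_X(path, fid, full, el)
    } else {
      h5_write_array(path, fid, full, el)
    }
  }
}

#' Write an AnnData .h5ad file
#'
#' Writes a cells x genes matrix with per-cell (`obs`) and per-gene (`var`)
#' tables, optional `layers`, `obsm` and `uns`, using the AnnData on-disk
#' encoding so the file opens directly in Python (`anndata.read_h5ad`) as
#' well as through [read_h5ad()].
#'
#' @param path Output path.
#' @param X Cells x genes matrix (dense or `dgCMatrix`; sparse is stored as
#'   a `csc_matrix` group).
#' @param obs Data frame of per-cell annotations, rownames = cell ids.
#' @param var Data frame of per-gene annotations, rownames = gene names.
#' @param layers Named list of cells x genes matrices.
#' @param obsm Named list of per-cell matrices (e.g. coordinates, features).
#' @param uns Named list of unstructured metadata (vectors/scalars).
#' @return `path`, invisibly.
#' @export
write_h5ad <- function(path, X, obs = NULL, var = NULL, layers = list(),
                       obsm = list(), uns = list()) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  fid <- h5_attr_queue()
  if (is.null(obs)) obs <- data.frame(row.names = rownames(X) %||% as.character(seq_len(nrow(X))))
  if (is.null(var)) var <- data.frame(row.names = colnames(X) %||% as.character(seq_len(ncol(X))))
  stopifnot(nrow(obs) == nrow(X), nrow(var) == ncol(X))
  h5_write_X(path, fid, "X", X)
  h5_write_df(path, fid, "obs", obs)
  h5_write_df(path, fid, "var", var)
  h5_write_dict(path, fid, "layers", layers, as_matrix = TRUE)
  h5_write_dict(path, fid, "obsm", obsm, as_matrix = TRUE)
  h5_write_dict(path, fid, "uns", uns)
  h5_mark(fid, ".", "anndata", "0.1.0")
  h5_apply_attrs(path, fid)
  invisible(path)
}

h5_read_elem <- function(path, name) {
  at <- rhdf5::h5readAttributes(path, name)
  enc <- at[["encoding-type"]] %||% ""
  val <- rhdf5::h5read(path, name)
  if (identical(enc, "csc_matrix")) {
    shape <- as.integer(at[["shape"]])
    Matrix::sparseMatrix(i = as.integer(val$indices) + 1L,
                         p = as.integer(val$indptr),
                         x = as.numeric(val$data), dims = shape)
  } else if (is.matrix(val)) {
    t(val)
  } else {
    val
  }
}

h5_read_df <- function(path, name) {
  at <- rhdf5::h5readAttributes(path, name)
  cols <- as.character(at[["column-order"]] %||% character(0))
  idx <- as.character(rhdf5::h5read(path, paste0(name, "/", at[["_index"]])))
  df <- data.frame(row.names = idx)
  for (col in cols) df[[col]] <- as.vector(rhdf5::h5read(path, paste0(name, "/", col)))
  df
}

#' @rdname write_h5ad
#' @return `read_h5ad` returns a list with elements `X`, `obs`, `var`,
#'   `layers`, `obsm`, `uns`.
#' @export
read_h5ad <- function(path) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  top <- rhdf5::h5ls(path, recursive = FALSE)$name
  read_dict <- function(name) {
    if (!name %in% top) return(list())
    ls_all <- rhdf5::h5ls(path)
    sub <- ls_all$name[ls_all$group == paste0("/", name)]
    out <- lapply(sub, function(k) h5_read_elem(path, paste0(name, "/", k)))
    names(out) <- sub
    out
  }
  X <- h5_read_elem(path, "X")
  obs <- h5_read_df(path, "obs")
  var <- h5_read_df(path, "var")
  dimnames(X) <- list(rownames(obs), rownames(var))
  list(X = X, obs = obs, var = var,
       layers = lapply(read_dict("layers"), function(m) {
         dimnames(m) <- list(rownames(obs), rownames(var)); m }),
       obsm = read_dict("obsm"),
       uns = read_dict("uns"))
}
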