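#' Serialize a fitted model to a self-describing text file
#'
#' Writes a single structured key-value text document containing the
#' feature definitions and scaling bounds, weights, regularization vector,
#' normalizer, entropy, the training-landscape raw-output distribution
#' (needed for the cumulative scale) and the training presence scores
#' (needed for thresholding) — everything projection and thresholding need,
#' so a reloaded model is self-contained. Numbers use 17 significant
#' digits, so save-then-load reproduces predictions bit-identically.
#'
#' @param model a `maxent_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "maxent_model"))
  num <- function(v) paste(sprintf("%.17g", v), collapse = "\t")
  chr <- function(v) paste(v, collapse = "\t")
  tab <- model$spec$table
  lines <- c(
    "flyclim_model\t1",
    paste0("species\t", model$species %||% "species"),
    paste0("variables\t", chr(model$spec$variables)),
    paste0("kinds\t", chr(model$spec$kinds)),
    paste0("clamp\t", as.integer(model$spec$clamp)),
    paste0("feature_name\t", chr(tab$name)),
    paste0("feature_kind\t", chr(tab$kind)),
    paste0("feature_var1\t", chr(tab$var1)),
    paste0("feature_var2\t", chr(ifelse(is.na(tab$var2), ".", tab$var2))),
    paste0("fmin\t", num(model$spec$fmin)),
    paste0("fmax\t", num(model$spec$fmax)),
    paste0("lambda\t", num(model$lambda)),
    paste0("beta\t", num(model$beta)),
    paste0("reg_multiplier\t", num(model$reg_multiplier)),
    paste0("c0\t", num(model$c0)),
    paste0("logZ\t", num(model$logZ)),
    paste0("entropy\t", num(model$entropy)),
    paste0("objective\t", num(model$objective)),
    paste0("landscape_cells\t", paste(model$landscape_cells,
                                      collapse = "\t")),
    paste0("landscape_raw_sorted\t", num(model$landscape_raw_sorted)),
    paste0("presence_cells\t", paste(model$presence_cells, collapse = "\t")),
    paste0("training_presence_raw\t", num(model$training_presence_raw))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Load a model written by [write_model()]
#' @param path model file path.
#' @return a `maxent_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (parts[[1L]][1L] != "flyclim_model") {
    stop(sprintf("%s is not a flyclim model file", path), call. = FALSE)
  }
  kv <- stats::setNames(lapply(parts, `[`, -1L),
                        vapply(parts, `[`, character(1L), 1L))
  num <- function(k) as.numeric(kv[[k]])
  chr <- function(k) as.character(kv[[k]])
  var2 <- chr("feature_var2")
  tab <- data.frame(name = chr("feature_name"), kind = chr("feature_kind"),
                    var1 = chr("feature_var1"),
                    var2 = ifelse(var2 == ".", NA_character_, var2),
                    stringsAsFactors = FALSE)
  spec <- structure(
    list(variables = chr("variables"), kinds = chr("kinds"), table = tab,
         fmin = stats::setNames(num("fmin"), tab$name),
         fmax = stats::setNames(num("fmax"), tab$name),
         clamp = as.logical(as.integer(kv[["clamp"]]))),
    class = "feature_spec")
  structure(
    list(species = if (!is.null(kv[["species"]])) chr("species")
                   else "species",
         spec = spec, lambda = num("lambda"), beta = num("beta"),
         reg_multiplier = num("reg_multiplier"), c0 = num("c0"),
         logZ = num("logZ"), entropy = num("entropy"),
         landscape_cells = as.integer(kv[["landscape_cells"]]),
         landscape_raw_sorted = num("landscape_raw_sorted"),
         presence_cells = as.integer(kv[["presence_cells"]]),
         training_presence_raw = num("training_presence_raw"),
         objective = num("objective"), iterations = NA_integer_,
         converged = TRUE),
    class = "maxent_model")
}
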