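# Shared fixtures, generated once per test session. Everything is built
# in code under tempdir(); nothing binary ships with the package.

.fixture_cache <- new.env(parent = emptyenv())

fixture_suite <- function() {
  if (is.null(.fixture_cache$suite)) {
    root <- file.path(tempdir(), "mids-fixture-suite")
    unlink(root, recursive = TRUE)
    make_fixture_suite(root, seed = 42L)
    .fixture_cache$suite <- root
  }
  .fixture_cache$suite
}

# a converted dataset built from the fixture suite (patient+extra sidecars on)
converted_root <- function() {
  if (is.null(.fixture_cache$converted)) {
    out <- file.path(tempdir(), "mids-converted")
    unlink(out, recursive = TRUE)
    convert_dicom_dataset(fixture_suite(), out, subject = "01")
    write_participants(
      data.frame(participant_id = "sub-01", age = 54, dominant_side = "R"),
      out)
    .fixture_cache$converted <- out
  }
  .fixture_cache$converted
}

# deep-copy a converted tree into a fresh directory for mutation tests
copy_tree <- function(src) {
  dst <- tempfile("mids-mut-")
  dir.create(dst)
  for (f in list.files(src, recursive = TRUE)) {
    dir.create(dirname(file.path(dst, f)), recursive = TRUE,
               showWarnings = FALSE)
    file.copy(file.path(src, f), file.path(dst, f))
  }
  dst
}

# every valid entity-key combination over the full suffix registry
all_valid_keys <- function() {
  reg <- suffix_registry()
  keys <- list()
  for (i in seq_len(nrow(reg))) {
    for (ses in list(NULL, "a")) {
      parts <- if (reg$part_allowed[i]) list(NULL, "mag", "phase", "real",
                                             "imag") else list(NULL)
      for (p in parts) {
        keys[[length(keys) + 1L]] <- entity_key(
          subject = "01", suffix = reg$suffix[i], session = ses, part = p)
      }
    }
  }
  keys
}

python_bin <- function() Sys.which("python")
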