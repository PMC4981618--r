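# shared fixtures: all built in code at test time

# minimal valid volume with reproducible content
rand_volume <- function(shape = c(8, 8, 8), spacing = c(1, 1, 1), seed = 1) {
  set.seed(seed)
  volume(array(stats::rnorm(prod(shape), 100, 10), dim = shape), spacing)
}

full_mask <- function(shape = c(8, 8, 8), spacing = c(1, 1, 1)) {
  binary_mask(array(1L, dim = shape), spacing)
}

# tissue label object from a raw integer array
tissue_labels_obj <- function(lab, spacing = c(1, 1, 1)) {
  structure(list(labels = lab, spacing = spacing),
            class = "wml_tissue_labels")
}

# lesion object directly from a label array
lesions_from_labels <- function(lab, spacing = c(1, 1, 1)) {
  attr(lab, "n_components") <- max(lab)
  wmlseg:::new_lesions(lab, spacing, 26L)
}

# standard small phantom for pipeline tests: 5 well-separated deep WM lesions
clean_phantom <- function(shape = c(64, 64, 64), seed = 3,
                          sizes = c(4, 8, 15, 22, 30)) {
  generate_phantom(phantom_spec(
    shape = shape,
    lesions = lapply(sizes, function(k)
      list(n_voxels = k, offset = 6, placement = "deep")),
    seed = seed))
}

# pure-R flood fill from the border: independent oracle for hole filling
flood_fill_oracle <- function(mask) {
  d <- dim(mask)
  outside <- array(FALSE, dim = d)
  queue <- list()
  push_if <- function(co) {
    if (all(co >= 1) && all(co <= d) &&
        mask[co[1], co[2], co[3]] == 0 && !outside[co[1], co[2], co[3]]) {
      outside[co[1], co[2], co[3]] <<- TRUE
      queue[[length(queue) + 1L]] <<- co
    }
  }
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3])
    if (x %in% c(1, d[1]) || y %in% c(1, d[2]) || z %in% c(1, d[3]))
      push_if(c(x, y, z))
  while (length(queue)) {
    co <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    for (delta in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                       c(0, 0, 1), c(0, 0, -1)))
      push_if(co + delta)
  }
  array(as.integer(mask == 1 | !outside), dim = d)
}
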