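# Shared, lazily built fixtures. The expensive ones (reconstructions) are
# cached so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures))
    assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# default-geometry thorax on a 32-slice grid
fx_phantom32 <- function() fixture("phantom32", function()
  generate_phantom(phantom_config(grid_shape = c(128L, 128L, 32L)),
                   seed = 5))

# 16-slice slab around the LV of fx_phantom32, with true mu-map, noiseless
# emission sinogram and the standard reconstructions
fx_slab <- function() fixture("slab", function() {
  ph <- fx_phantom32()
  zmy <- which(apply(ph$masks$myocardium, 3, any))
  z0 <- max(1, min(zmy) - 3L); z1 <- z0 + 15L
  act <- crop_z(ph$activity, c(z0, z1))
  lab <- crop_z(ph$labels, c(z0, z1))
  mu <- labels_to_mu(lab)
  proto <- recon_protocol()
  sino <- forward_project(act, mu, proto)
  list(phantom = ph, activity = act, labels = lab, mu = mu,
       myo = ph$masks$myocardium[, , z0:z1], sino = sino, proto = proto)
})

fx_recon_true <- function() fixture("recon_true", function() {
  s <- fx_slab()
  reconstruct_osem(s$sino, s$mu, s$proto)
})

fx_nonac32 <- function() fixture("nonac32", function() {
  ph <- fx_phantom32()
  mu <- labels_to_mu(ph$labels)
  sino <- forward_project(ph$activity, mu, recon_protocol())
  reconstruct_osem(sino, NULL, recon_protocol())
})

# small uniform soft-tissue block for fill/injection unit tests
fx_block <- function(n = 16L) {
  g <- grid_spec(rep(n, 3), c(2.6, 2.6, 2.6))
  label_map(array(3L, g$shape), g)
}
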