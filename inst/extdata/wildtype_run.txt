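# Wild-type simulation: calibrated defaults, 150-cell tissue, 80 min
# observation after a 20 min burn-in, frames every 30 s.
init = voronoi
n_cells = 150
duration = 80
burn_in = 20
frame_interval = 0.5
seed = 1
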