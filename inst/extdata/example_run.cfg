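# fcdyn run configuration (flat key = value; '#' starts a comment)
# paths are resolved relative to the working directory
topology   = fixture/system.pdb
trajectory = fixture/traj.dcd
glycoform  = Man8
chains     = A,B
out_dir    = fcdyn_out

# descriptor parameters (Angstrom unless noted)
contact_cutoff   = 4.5
detach_threshold = 9.0
window_fraction  = 0.75
frame_dt_ns      = 0.24

# loop classifier
loop_resno     = 295:299
fit_resno      = 259:265,301:306
c_prime_resno  = 290:294
e_strand_resno = 304:308
r_native       = 3.0
s_min          = 0.5
pair_tol       = 6.5

# domains and interface
cg2_resno = 238:340
cg3_resno = 341:443
interface_resno_A = 295:299
interface_resno_B = 295:299

convergence_tol  = 0.5
min_event_frames = 1
seed = 1
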