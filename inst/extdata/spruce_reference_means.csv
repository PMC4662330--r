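trait,canopy,treatment,mean,ci_lo,ci_hi,scale,unit
A_lum,shade,control,14.5,9.6,19.5,1,um2
A_lum,shade,drought,13.1,8.2,18.0,1,um2
A_lum,sun,control,20.2,15.2,25.1,1,um2
A_lum,sun,drought,16.3,11.3,21.2,1,um2
A_n,shade,control,0.35,0.29,0.42,1,mm2
A_n,shade,drought,0.34,0.28,0.40,1,mm2
A_n,sun,control,0.76,0.69,0.82,1,mm2
A_n,sun,drought,0.63,0.57,0.69,1,mm2
A_p,shade,control,12.7,7.4,18.0,1e2,um2
A_p,shade,drought,13.1,7.8,18.4,1e2,um2
A_p,sun,control,29.4,24.0,34.5,1e2,um2
A_p,sun,drought,28.7,23.4,34.1,1e2,um2
A_p_pct,shade,control,0.37,0.27,0.47,1,%
A_p_pct,shade,drought,0.39,0.30,0.50,1,%
A_p_pct,sun,control,0.39,0.29,0.49,1,%
A_p_pct,sun,drought,0.47,0.36,0.56,1,%
A_v,shade,control,19,14,24,1e-3,mm2
A_v,shade,drought,17,12,22,1e-3,mm2
A_v,sun,control,48,43,53,1e-3,mm2
A_v,sun,drought,42,37,47,1e-3,mm2
A_x,shade,control,9.3,6.5,12.1,1e2,um2
A_x,shade,drought,9.0,6.2,11.7,1e2,um2
A_x,sun,control,20.6,17.8,23.4,1e2,um2
A_x,sun,drought,17.0,14.2,19.7,1e2,um2
A_x_pct,shade,control,0.27,0.22,0.33,1,%
A_x_pct,shade,drought,0.27,0.21,0.32,1,%
A_x_pct,sun,control,0.27,0.22,0.33,1,%
A_x_pct,sun,drought,0.27,0.21,0.32,1,%
d_max,shade,control,5.2,4.4,6.0,1,um
d_max,shade,drought,4.9,4.1,5.7,1,um
d_max,sun,control,6.2,5.4,7.0,1,um
d_max,sun,drought,5.6,4.8,6.4,1,um
d_min,shade,control,3.4,2.9,3.9,1,um
d_min,shade,drought,3.2,2.7,3.7,1,um
d_min,sun,control,3.8,3.3,4.3,1,um
d_min,sun,drought,3.5,3.0,3.9,1,um
F_t,shade,control,1.61,1.55,1.66,1,ratio
F_t,shade,drought,1.60,1.55,1.66,1,ratio
F_t,sun,control,1.75,1.69,1.81,1,ratio
F_t,sun,drought,1.72,1.67,1.77,1,ratio
k_th,shade,control,18,10,32,1e-11,kg m s-1 MPa-1
k_th,shade,drought,14,8,26,1e-11,kg m s-1 MPa-1
k_th,sun,control,61,34,109,1e-11,kg m s-1 MPa-1
k_th,sun,drought,36,20,64,1e-11,kg m s-1 MPa-1
k_s,shade,control,0.22,0.10,0.33,1e-12,kg m-1 s-1 MPa-1
k_s,shade,drought,0.18,0.06,0.30,1e-12,kg m-1 s-1 MPa-1
k_s,sun,control,0.34,0.23,0.46,1e-12,kg m-1 s-1 MPa-1
k_s,sun,drought,0.23,0.11,0.35,1e-12,kg m-1 s-1 MPa-1
N_lum,shade,control,291,145,437,1,um2
N_lum,shade,drought,263,118,409,1,um2
N_lum,sun,control,713,567,860,1,um2
N_lum,sun,drought,519,373,665,1,um2
N_t,shade,control,20.4,18.2,22.6,1,count
N_t,shade,drought,20.0,17.9,22.1,1,count
N_t,sun,control,35.1,32.8,37.5,1,count
N_t,sun,drought,31.9,29.7,34.1,1,count
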