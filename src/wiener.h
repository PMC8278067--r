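#pragma once

// First-passage density machinery for the constant-drift Wiener process with
// unit diffusion, absorbing boundaries at 0 and a, start point w * a.

double wiener_fpt_std(double u, double w, double eps);
double wiener_lpdf_lower(double t, double v, double a, double w, double eps);
double wiener_lpdf(double t, double v, double a, double w, bool upper,
                   double eps);
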