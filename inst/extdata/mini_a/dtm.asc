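NCOLS 18
NROWS 18
XLLCORNER 975
YLLCORNER 975
CELLSIZE 25
NODATA_VALUE -9999
         99         101         103         105         107         109         111         113         115         117         119         121         123         125         127         129         131         133
         99         101         103         105         107         109         111         113         115         117         119         121         123         125         127         129         131         133
         99         101         103         105         107         109         111         113         115         117         119         121         123         125         127         129         131         133
         99         101         103         105         107         109         111         113         115         117         119         121         123         125         127         129         131         133
         99         101         103         105         107         109         111         113         115         117         119         121         123         125         127         129         131         133
         99         101         103         105         107         109         111         113         115         117         119         121         123         125         127         129         131         133
         99         101         103         105         107         109         111         113         115         117         119         121         123         125         127         129         131         133
         99         101         103         105         107         109         111         113         115         117         119         121         123         125         127         129         131         133
         99         101         103         105         107         109         111         113         115         117         119         121         123         125         127         129         131         133
         99         101         103         105         107         109         111         113         115         117         119         121         123         125         127         129         131         133
         99         101         103         105         107         109         111         113         115         117         119         121         123         125         127         129         131         133
         99         101         103         105         107         109         111         113         115         117         119         121         123         125         127         129         131         133
         99         101         103         105         107         109         111         113         115         117         119         121         123         125         127         129         131         133
         99         101         103         105         107         109         111         113         115         117         119         121         123         125         127         129         131         133
         99         101         103         105         107         109         111         113         115         117         119         121         123         125         127         129         131         133
         99         101         103         105         107         109         111         113         115         117         119         121         123         125         127         129         131         133
         99         101         103         105         107         109         111         113         115         117         119         121         123         125         127         129         131         133
         99         101         103         105         107         109         111         113         115         117         119         121         123         125         127         129         131         133
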