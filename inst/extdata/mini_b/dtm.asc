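NCOLS 18
NROWS 18
XLLCORNER 975
YLLCORNER 975
CELLSIZE 25
NODATA_VALUE -9999
        100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100
        100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100
        100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100
        100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100
        100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100
        100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100
        100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100
        100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100
        100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100
        100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100
        100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100
        100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100
        100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100
        100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100
        100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100
        100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100
        100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100
        100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100         100
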