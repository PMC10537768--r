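ply
format ascii 1.0
comment synthetic fixture: vertices with colour properties
element vertex 4
property float x
property float y
property float z
property uchar red
property uchar green
property uchar blue
end_header
0.5 -0.25 1.125 255 0 0
-1.5 2 0.375 0 255 0
3.25 0 -0.5 0 0 255
0 0.125 2.5 128 128 128
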