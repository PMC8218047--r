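question,ct,f3d,xb,count
detection,without,high,high,1103
detection,without,high,low,141
detection,without,low,high,303
detection,without,low,low,505
detection,with,high,high,1290
detection,with,high,low,135
detection,with,low,high,215
detection,with,low,low,412
classification,without,high,high,156
classification,without,high,low,79
classification,without,low,high,392
classification,without,low,low,963
classification,with,high,high,706
classification,with,high,low,157
classification,with,low,high,270
classification,with,low,low,509
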