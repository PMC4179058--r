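name,range,stage,tp,fp,fn,tn
close_knn,3-10,per_frame,2056,332,330,1663
close_track,3-10,tracked,2167,76,219,1919
far_knn,10-20,per_frame,2735,515,1606,3600
far_track,10-20,tracked,2753,331,1588,3784
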