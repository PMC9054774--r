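name,type,v_min_ms,v_max_ms,v_min_sink_ms,v_theta_min_ms,ld_max,theta_min_deg
Pigeon (Columba livia),bird,8,22,,,6,9.5
Laggar falcon (Falco jugger),bird,6.6,15.9,,12.5,10,5.7
Black vulture (Coragyps atratus),bird,9.9,16.8,11.6,13.9,11.6,4.9
Harris hawk (Parabuteo unicinctus),bird,6.1,16.2,8.8,,10.9,5.2
Jackdaw (Corvus monedula),bird,6,11,7.4,8.3,12.6,4.5
Common swift (Apus apus),bird,7,11,8.1,9.4,12.5,4.6
Astro-mite,uav,6,9.5,,,10,5.7
Dream-flight Alula,uav,4.7,13,5,6.5,12,4.8
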