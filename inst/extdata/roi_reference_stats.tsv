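name	acronym	g_mean	g_sd	avf_mean	avf_sd	mvf_mean	mvf_sd
Anterior limb of internal capsule right	ACL r	0.688	0.029	0.384	0.052	0.419	0.022
Retrolenticular part of internal capsule left	RIC l	0.665	0.020	0.341	0.025	0.428	0.023
Anterior corona radiata right	ACR r	0.651	0.012	0.321	0.014	0.435	0.014
Anterior corona radiata left	ACR l	0.644	0.015	0.313	0.014	0.440	0.018
Superior corona radiata right	SCR r	0.679	0.014	0.356	0.018	0.413	0.087
Superior corona radiata left	SCR l	0.674	0.013	0.350	0.016	0.419	0.017
Genu of corpus callosum	GCC	0.642	0.020	0.315	0.021	0.445	0.024
Body of corpus callosum	BCC	0.657	0.021	0.328	0.025	0.425	0.020
Posterior corona radiata right	PCR r	0.662	0.019	0.326	0.025	0.416	0.019
Posterior corona radiata left	PCR l	0.667	0.018	0.337	0.023	0.418	0.019
Posterior thalamic radiation right	PTR r	0.643	0.016	0.308	0.017	0.438	0.018
Posterior thalamic radiation left	PTR l	0.645	0.017	0.313	0.016	0.438	0.020
Sagittal stratum left	SAS l	0.645	0.021	0.314	0.020	0.439	0.025
External capsule right	EXC r	0.683	0.020	0.359	0.023	0.410	0.028
External capsule left	EXC l	0.682	0.025	0.357	0.023	0.408	0.034
Cingulum left	CGM l	0.661	0.023	0.330	0.028	0.422	0.029
Fornix/Stria terminalis left	FNX l	0.669	0.027	0.349	0.036	0.426	0.028
Superior longitudinal fasciculus right	SLF r	0.666	0.016	0.334	0.017	0.418	0.022
Superior longitudinal fasciculus left	SLF l	0.668	0.013	0.340	0.015	0.420	0.020
Superior fronto-occipital fasciculus right	SFO r	0.678	0.020	0.361	0.031	0.422	0.020
Superior fronto-occipital fasciculus left	SFO l	0.672	0.021	0.350	0.029	0.424	0.020
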